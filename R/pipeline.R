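# End-to-end batch driver: QC -> alignment -> projection -> watershed body
# model -> sex call -> interocular distance -> wing fitting, emitting one
# measurement row per fly.

#' Align the valid frames of a sequence
#'
#' Background-subtracts and complements the blue channel of the selected
#' frames and aligns them (and the matching red frames) by central image
#' moments.
#'
#' @param seq a `frame_sequence`.
#' @param valid_idx indices of the frames to use (e.g. from
#'   [accept_sequence()]).
#' @return an `aligned_stack` carrying `mm_per_px`.
#' @export
#' @param crop crop the working region to the union fly bounding box (plus
#'   a rotation-safe margin) before aligning; the frames of the returned
#'   stack are then crops, which speeds up every downstream stage.
align_sequence <- function(seq, valid_idx, crop = TRUE) {
  stopifnot(length(valid_idx) >= 1)
  comp <- lapply(seq$frames[valid_idx], function(fr)
    subtract_and_complement(fr$blue, seq$background$blue))
  reds <- lapply(seq$frames[valid_idx], `[[`, "red")
  offset <- c(0L, 0L)                    # (row0, col0) of the crop
  if (crop) {
    dark <- Reduce(pmin, comp)
    fg <- dark < 1 - 0.08
    if (any(fg)) {
      margin <- 45
      rows <- clamp(range(which(rowSums(fg) > 0)) + c(-margin, margin),
                    1, nrow(dark))
      cols <- clamp(range(which(colSums(fg) > 0)) + c(-margin, margin),
                    1, ncol(dark))
      ri <- rows[1]:rows[2]; ci <- cols[1]:cols[2]
      comp <- lapply(comp, function(m) m[ri, ci, drop = FALSE])
      reds <- lapply(reds, function(m) m[ri, ci, drop = FALSE])
      offset <- c(rows[1] - 1L, cols[1] - 1L)
    }
  }
  st <- moments_align(comp, red_images = reds)
  st$mm_per_px <- seq$mm_per_px %||% NA
  st$crop_offset <- offset
  st$frame_indices <- valid_idx
  st
}

#' Analyze one fly sequence
#'
#' Runs the full measurement pipeline on one sequence. A failed stage
#' (e.g. ocelli not found) yields a partial record with `NA` fields and a
#' note, not an error.
#'
#' @param seq a `frame_sequence`.
#' @param config an [fw_config()].
#' @param fly_id identifier for the output row.
#' @param templates sex templates (see [sex_templates()]); `NULL` disables
#'   the luminance route (comb-only sexing).
#' @return list with `record` (one-row data.frame), `decision`, `qc`,
#'   `body_model`, `sex`, `head`, `wing`, `notes`.
#' @export
analyze_sequence <- function(seq, config = fw_config(), fly_id = NA,
                             templates = sex_templates()) {
  notes <- character(0)
  qc <- qc_sequence(seq, config)
  decision <- accept_sequence(qc, config$qc$min_valid_frames)
  rec <- data.frame(
    fly_id = fly_id, accepted = decision$accepted,
    n_valid_frames = decision$n_valid,
    sex = NA_character_, sex_confidence = NA_real_,
    iod = NA_real_, sw = NA_real_,
    head_len = NA_real_, head_wid = NA_real_,
    thorax_len = NA_real_, thorax_wid = NA_real_,
    abd_len = NA_real_, abd_wid = NA_real_,
    wl = NA_real_, ww = NA_real_, wa = NA_real_,
    wing_side = NA_character_, wing_converged = NA,
    notes = "", stringsAsFactors = FALSE)
  empty <- list(record = rec, decision = decision, qc = qc,
                body_model = NULL, sex = NULL, head = NULL, wing = NULL)
  if (!decision$accepted) {
    rec$notes <- "insufficient valid frames"
    empty$record <- rec
    return(empty)
  }
  res <- empty
  stack <- align_sequence(seq, decision$valid_frame_indices)
  body_model <- tryCatch({
    proj <- percentile_projection(stack, q = config$body$percentile)
    mask <- binarize_and_close(proj, config$body$threshold,
                               config$body$closing_radius,
                               config$body$min_area)
    segs <- watershed_segments(mask, config$body$min_peak_separation,
                               red_frame = stack$red_frames[[1]])
    fit_segment_templates(segs)
  }, error = function(e) {
    notes <<- c(notes, paste("body:", conditionMessage(e)))
    NULL
  })
  res$body_model <- body_model
  if (!is.null(body_model)) {
    rec$head_len <- body_model$head$length
    rec$head_wid <- body_model$head$width
    rec$thorax_len <- body_model$thorax$length
    rec$thorax_wid <- body_model$thorax$width
    rec$abd_len <- body_model$abdomen$length
    rec$abd_wid <- body_model$abdomen$width
    rec$sw <- shoulder_width(body_model$thorax)

    sx <- tryCatch(call_sex(stack, body_model, templates, config),
                   error = function(e) {
                     notes <<- c(notes, paste("sex:", conditionMessage(e)))
                     NULL
                   })
    res$sex <- sx
    if (!is.null(sx)) {
      rec$sex <- sx$sex
      rec$sex_confidence <- max(sx$lum_confidence, sx$comb_confidence)
    }

    hd <- tryCatch(measure_head(stack, body_model, config),
                   error = function(e) {
                     notes <<- c(notes, paste("head:", conditionMessage(e)))
                     NULL
                   })
    res$head <- hd
    if (!is.null(hd)) rec$iod <- hd$iod_px

    wg <- tryCatch(suppressWarnings(measure_wings(stack, body_model, config)),
                   error = function(e) {
                     notes <<- c(notes, paste("wing:", conditionMessage(e)))
                     NULL
                   })
    res$wing <- wg
    if (!is.null(wg)) {
      rec$wl <- wg$wl_px
      rec$ww <- wg$ww_px
      rec$wa <- wg$wa_px2
      rec$wing_side <- wg$side
      rec$wing_converged <- wg$converged
    } else {
      notes <- c(notes, "wing: not fitted")
    }
  }
  rec$notes <- paste(notes, collapse = "; ")
  res$record <- rec
  res
}

#' Analyze a batch of sequences
#'
#' Processes every fly sequence found in `input_dir` (multi-page TIFFs or
#' PNG directories named `fly_*`), or a list of in-memory sequences.
#' Accepted flies get sequential storage-well indices in acceptance order;
#' rejected flies keep a row with the rejection reason. Writes
#' `measurements.csv` and `qc.csv` into `out_dir` when given.
#'
#' @param input sequence directory, or a list of `frame_sequence` objects.
#' @param config an [fw_config()].
#' @param out_dir optional output directory for the CSVs.
#' @param templates sex templates, see [sex_templates()].
#' @param mm_per_px pixel calibration applied to mm columns (from config by
#'   default).
#' @return list with `measurements` (data.frame, one row per fly, px and mm
#'   columns) and `qc` (per-frame QC table).
#' @export
analyze_batch <- function(input, config = fw_config(), out_dir = NULL,
                          templates = sex_templates(),
                          mm_per_px = config$mm_per_px) {
  if (is.character(input)) {
    listing <- list_sequences(input)
    if (nrow(listing) == 0) stop("no fly sequences found in ", input)
    seqs <- lapply(listing$path, read_sequence, mm_per_px = mm_per_px)
    ids <- listing$fly_id
  } else {
    seqs <- input
    ids <- if (!is.null(names(input))) names(input)
           else sprintf("fly_%03d", seq_along(input))
  }
  rows <- list(); qcs <- list()
  well <- 0L
  for (i in seq_along(seqs)) {
    res <- analyze_sequence(seqs[[i]], config, fly_id = ids[i],
                            templates = templates)
    rec <- res$record
    if (rec$accepted) {
      well <- well + 1L
      rec$well_index <- well
      if (well > config$select$capacity) {
        warning("storage capacity (", config$select$capacity, ") exceeded")
      }
    } else {
      rec$well_index <- NA_integer_
    }
    rows[[i]] <- rec
    qcs[[i]] <- qc_report(res$qc, fly_id = ids[i])
  }
  meas <- do.call(rbind, rows)
  # mm columns at report time
  meas$iod_mm <- meas$iod * mm_per_px
  meas$sw_mm <- meas$sw * mm_per_px
  meas$wl_mm <- meas$wl * mm_per_px
  meas$ww_mm <- meas$ww * mm_per_px
  meas$wa_mm2 <- meas$wa * mm_per_px^2
  meas$excluded <- FALSE
  meas$exclusion_reason <- ""
  qc_tab <- do.call(rbind, qcs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(qc_tab, file.path(out_dir, "qc.csv"), row.names = FALSE)
  }
  list(measurements = meas, qc = qc_tab)
}

#' End-to-end trait-recovery report
#'
#' Simulates `n` clean flies, analyzes them with the full pipeline, and
#' compares the recovered traits with the generator's ground truth: Pearson
#' correlation and residual SD (percent of truth, via the bi-square fit)
#' per trait, plus sex-call accuracy and unknown rate.
#'
#' @param n number of flies.
#' @param seed master seed (generator and renderer).
#' @param config an [fw_config()].
#' @param cfg a [render_config()] describing the imaging conditions.
#' @param sex population sex mix, see [render_population()].
#' @return list with `agreement` (per-trait data.frame), `sex_accuracy`,
#'   `unknown_rate`, `n_accepted`, `measurements`, `truth`.
#' @export
end_to_end_recovery_report <- function(n, seed, config = fw_config(),
                                       cfg = render_config(), sex = "mixed") {
  # flies are generated, analyzed and discarded one at a time: a full
  # two-channel sequence is ~100 MB, so a population never lives in memory
  templates <- sex_templates()
  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  well <- 0L
  for (i in seq_len(n)) {
    truth <- sample_fly(child_seed(seed, i),
                        sex = if (sex == "mixed") NULL else sex)
    cfg_i <- cfg
    cfg_i$seed <- child_seed(seed, 100000 + i)
    sq <- render_sequence(truth, cfg_i)
    res <- analyze_sequence(sq, config, fly_id = sprintf("fly_%03d", i),
                            templates = templates)
    rec <- res$record
    rec$well_index <- if (rec$accepted) (well <- well + 1L) else NA_integer_
    rows[[i]] <- rec
    truth_rows[[i]] <- truth_row(truth, fly_id = sprintf("fly_%03d", i))
    rm(sq, res)
  }
  meas <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  m <- merge(truth, meas, by = "fly_id")
  pairs <- list(wl = c("wl_px", "wl"), ww = c("ww_px", "ww"),
                wa = c("wa_px2", "wa"), iod = c("iod_px", "iod"),
                sw = c("sw_px", "sw"))
  agreement <- do.call(rbind, lapply(names(pairs), function(tr) {
    x <- m[[pairs[[tr]][1]]]; y <- m[[pairs[[tr]][2]]]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3) {
      return(data.frame(trait = tr, n = sum(keep), r = NA, mean_pct = NA,
                        sd_pct = NA))
    }
    rep <- agreement_report(x[keep], y[keep], trait = tr)
    data.frame(trait = tr, n = rep$n, r = rep$r, mean_pct = rep$mean_pct,
               sd_pct = rep$sd_pct)
  }))
  called <- m$sex.y[m$accepted]
  truth_sex <- m$sex.x[m$accepted]
  known <- !is.na(called) & called != "unknown"
  list(agreement = agreement,
       sex_accuracy = if (any(known)) mean(called[known] == truth_sex[known])
                      else NA_real_,
       unknown_rate = mean(!known),
       n_accepted = sum(m$accepted),
       measurements = meas, truth = truth)
}

#' Export a fit-overlay image
#'
#' Renders the aligned projection with the fitted segment ellipses, wing
#' splines and head landmarks for visual verification, as a PNG.
#'
#' @param res result list from [analyze_sequence()].
#' @param stack the `aligned_stack` used (recomputed when `NULL`).
#' @param seq the original `frame_sequence` (needed when `stack` is `NULL`).
#' @param path output PNG path.
#' @export
write_overlay <- function(res, path, stack = NULL, seq = NULL) {
  if (is.null(stack)) {
    stopifnot(!is.null(seq))
    stack <- align_sequence(seq, res$decision$valid_frame_indices)
  }
  proj <- percentile_projection(stack)
  grDevices::png(path, width = ncol(proj), height = nrow(proj))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(t(proj)[, nrow(proj):1], col = grDevices::gray.colors(256),
                  axes = FALSE, useRaster = TRUE)
  to_plot <- function(p) cbind(p[, 1] / ncol(proj), 1 - p[, 2] / nrow(proj))
  if (!is.null(res$wing)) {
    out <- eval_bspline_curve(res$wing$outline, seq(0, 1, length.out = 256))
    graphics::lines(to_plot(out), col = "yellow")
    for (v in res$wing$veins) {
      graphics::lines(to_plot(eval_bspline_curve(v, seq(0, 1, length.out = 64))),
                      col = "yellow")
    }
  }
  if (!is.null(res$head)) {
    graphics::points(to_plot(res$head$eye_edges), col = "red", pch = 3)
    graphics::points(to_plot(res$head$ocelli_posterior), col = "cyan", pch = 1)
  }
  invisible(path)
}
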