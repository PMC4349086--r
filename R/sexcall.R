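# Sex discrimination: abdominal-luminance template correlation fused with
# sex-comb detection. Combs only exist in males, so positive comb evidence
# dominates; the luminance route carries female calls and backs up males.

#' Abdominal luminance profile
#'
#' Samples the red-channel luminance along the abdomen segment's major
#' (vertical) axis, averaging over a small transverse band inside the
#' abdomen, resamples to `n_samples` points on normalized arc length
#' \[0, 1\] (anterior to posterior) and divides by the mean, so the profile
#' is invariant to abdomen size and overall illumination.
#'
#' @param red_frame aligned red-channel matrix.
#' @param abdomen_segment logical mask of the abdomen segment (aligned).
#' @param n_samples resampling length (default 100).
#' @param min_area degenerate-segment guard.
#' @return object of class `luminance_profile`: `positions` (strictly
#'   increasing in \[0, 1\]), `values` (mean 1), `n_samples`.
#' @export
abdominal_profile <- function(red_frame, abdomen_segment, n_samples = 100,
                              min_area = 200) {
  if (sum(abdomen_segment) < min_area) stop("abdomen segment too small")
  rows <- which(rowSums(abdomen_segment) > 0)
  vals <- vapply(rows, function(r) {
    sel <- abdomen_segment[r, ]
    mean(red_frame[r, sel])
  }, numeric(1))
  u <- (rows - min(rows)) / (max(rows) - min(rows))
  pos <- seq(0, 1, length.out = n_samples)
  v <- stats::approx(u, vals, xout = pos, rule = 2)$y
  m <- mean(v)
  if (m <= 0) stop("abdomen luminance is zero")
  structure(list(positions = pos, values = v / m, n_samples = n_samples),
            class = "luminance_profile")
}

#' Correlate a profile against the sex templates
#'
#' Zero-lag Pearson correlation of the profile against the average male and
#' female luminance curves (profiles are arc-length normalized, so no lag
#' search is needed). The candidate sex is the template with the higher
#' coefficient.
#'
#' @param profile a `luminance_profile` (or numeric vector).
#' @param tpl_male,tpl_female templates at the same resampling length.
#' @return list `(r_male, r_female)`; a constant profile yields 0 with a
#'   warning.
#' @export
correlate_templates <- function(profile, tpl_male, tpl_female) {
  v <- if (inherits(profile, "luminance_profile")) profile$values else profile
  tm <- if (inherits(tpl_male, "luminance_profile")) tpl_male$values else tpl_male
  tf <- if (inherits(tpl_female, "luminance_profile")) tpl_female$values else tpl_female
  stopifnot(length(v) == length(tm), length(v) == length(tf))
  warned <- FALSE
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
      if (!warned) {
        warning("constant profile: correlation undefined, set to 0")
        warned <<- TRUE
      }
      return(0)
    }
    stats::cor(a, b)
  }
  list(r_male = safe_cor(v, tm), r_female = safe_cor(v, tf))
}

#' Detect sex combs anterior to the head
#'
#' Scans each aligned frame in the region extending anterior to the head
#' along the body axis, thresholds the red channel for dark spots, and keeps
#' compact blobs: candidate regions with area inside `area_range` and
#' second-moment eccentricity below `eccentricity_max` (elongated objects -
#' legs crossing the antennae - are rejected). Comb confidence combines the
#' fraction of frames with a detection and the mean detected area.
#'
#' @param red_frames list of aligned red-channel matrices.
#' @param body_model a `body_model` (for the head position).
#' @param config an [fw_config()].
#' @return list `(comb_detected, comb_confidence, detections)` where
#'   `detections` is a per-frame list of kept blob properties.
#' @export
detect_sex_combs <- function(red_frames, body_model, config = fw_config()) {
  sx <- config$sex
  labs <- body_model$labels
  head_rows <- which(rowSums(labs == 1) > 0)
  if (length(head_rows) == 0) {
    return(list(comb_detected = FALSE, comb_confidence = 0,
                detections = list()))
  }
  head_front <- min(head_rows)
  cx <- body_model$head$center[1]
  r0 <- max(1, head_front - 45)
  r1 <- min(nrow(labs), head_front + 5)
  c0 <- max(1, round(cx - 45)); c1 <- min(ncol(labs), round(cx + 45))
  if (r1 <= r0) {
    return(list(comb_detected = FALSE, comb_confidence = 0,
                detections = list()))
  }
  detections <- lapply(red_frames, function(fr) {
    roi <- fr[r0:r1, c0:c1, drop = FALSE]
    dark <- roi < sx$comb_threshold
    if (!any(dark)) return(list())
    lab <- from_ebimage(EBImage::bwlabel(as_ebimage(dark * 1)))
    props <- region_props(lab)
    keep <- Filter(function(p) {
      p$area >= sx$comb_area_range[1] && p$area <= sx$comb_area_range[2] &&
        p$eccentricity <= sx$eccentricity_max
    }, props)
    lapply(keep, function(p)
      list(area = p$area, eccentricity = p$eccentricity,
           center = p$centroid + c(c0 - 1, r0 - 1)))
  })
  hit <- vapply(detections, function(d) length(d) > 0, logical(1))
  if (!any(hit)) {
    return(list(comb_detected = FALSE, comb_confidence = 0,
                detections = detections))
  }
  areas <- unlist(lapply(detections[hit], function(d)
    vapply(d, `[[`, numeric(1), "area")))
  conf <- mean(hit) * min(1, mean(areas) / sx$comb_area_ref)
  list(comb_detected = TRUE, comb_confidence = clamp(conf, 0, 1),
       detections = detections)
}

#' Fuse luminance and comb evidence into a sex call
#'
#' Decision rule: a detected comb with confidence at least `tau_comb` calls
#' male (combs exist only in males); otherwise a luminance confidence
#' `|r_male - r_female|` of at least `tau_lum` calls the template with the
#' higher correlation; otherwise, with no comb found, a female-favouring
#' margin of at least `tau_lum / 2` still calls female (absence of a comb is
#' itself weak female evidence); anything else is `unknown`.
#'
#' @param lum_result list `(r_male, r_female)` from [correlate_templates()].
#' @param comb_result list from [detect_sex_combs()].
#' @param thresholds list with `tau_comb`, `tau_lum`.
#' @return object of class `sex_call`: `sex` (`"male"`, `"female"`,
#'   `"unknown"`), `r_male`, `r_female`, `lum_confidence`, `comb_detected`,
#'   `comb_confidence`.
#' @export
combine_evidence <- function(lum_result, comb_result,
                             thresholds = list(tau_comb = 0.3,
                                               tau_lum = 0.15)) {
  lum_conf <- clamp(abs(lum_result$r_male - lum_result$r_female), 0, 1)
  lum_sex <- if (lum_result$r_male >= lum_result$r_female) "male" else "female"
  sex <- "unknown"
  if (comb_result$comb_detected &&
      comb_result$comb_confidence >= thresholds$tau_comb) {
    sex <- "male"
  } else if (lum_conf >= thresholds$tau_lum) {
    sex <- lum_sex
  } else if (!comb_result$comb_detected && lum_sex == "female" &&
             lum_conf >= thresholds$tau_lum / 2) {
    sex <- "female"
  }
  structure(list(sex = sex, r_male = lum_result$r_male,
                 r_female = lum_result$r_female, lum_confidence = lum_conf,
                 comb_detected = comb_result$comb_detected,
                 comb_confidence = comb_result$comb_confidence),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf(
    "<sex_call> %s  (r_m=%.2f r_f=%.2f lum_conf=%.2f comb=%s conf=%.2f)\n",
    x$sex, x$r_male, x$r_female, x$lum_confidence,
    if (x$comb_detected) "yes" else "no", x$comb_confidence))
  invisible(x)
}

#' Call sex for an aligned sequence
#'
#' Convenience wrapper: profile on the brightest red frame, comb scan over
#' all aligned frames, fusion per [combine_evidence()].
#'
#' @param stack an `aligned_stack` with red frames.
#' @param body_model a `body_model`.
#' @param templates list with `male` and `female` profile templates; default
#'   the packaged generator-derived templates, see [sex_templates()].
#' @param config an [fw_config()].
#' @return a `sex_call`.
#' @export
call_sex <- function(stack, body_model, templates = sex_templates(),
                     config = fw_config()) {
  bright <- select_brightest_red_frame(stack, body_model)
  prof <- abdominal_profile(stack$red_frames[[bright]],
                            body_model$labels == 3,
                            n_samples = config$sex$n_samples)
  lum <- correlate_templates(prof, templates$male, templates$female)
  comb <- detect_sex_combs(stack$red_frames, body_model, config)
  combine_evidence(lum, comb, thresholds = list(
    tau_comb = config$sex$tau_comb, tau_lum = config$sex$tau_lum))
}

#' Packaged abdominal-luminance templates
#'
#' Average male and female abdominal luminance curves. The packaged default
#' (shipped as two-column CSVs under `extdata/`) was built by rendering 50
#' clean synthetic flies per sex and averaging their measured profiles;
#' users working with real imagery should replace them with templates
#' averaged from manually sexed flies via [build_sex_templates()].
#'
#' @param male,female optional paths to two-column (position, luminance)
#'   CSV files.
#' @return list with `male` and `female` numeric template vectors.
#' @export
sex_templates <- function(male = NULL, female = NULL) {
  read_tpl <- function(path) {
    df <- utils::read.csv(path)
    stats::approx(df[[1]], df[[2]], xout = seq(0, 1, length.out = 100),
                  rule = 2)$y
  }
  if (is.null(male)) {
    male <- system.file("extdata", "template_male.csv", package = "flywalk")
  }
  if (is.null(female)) {
    female <- system.file("extdata", "template_female.csv",
                          package = "flywalk")
  }
  list(male = read_tpl(male), female = read_tpl(female))
}

#' Build luminance templates from the generator
#'
#' Renders `n_per_sex` clean flies per sex, runs the body-segmentation
#' pipeline, and averages the measured abdominal profiles. Used to produce
#' the packaged templates; exposed so they can be rebuilt with other
#' population parameters.
#'
#' @param n_per_sex flies per sex (default 50).
#' @param seed master seed.
#' @param config an [fw_config()].
#' @param n_frames frames per fly (fewer than the default speeds this up).
#' @return list with `male`, `female` template vectors and `positions`.
#' @export
build_sex_templates <- function(n_per_sex = 50, seed = 424243,
                                config = fw_config(), n_frames = 4) {
  one_sex <- function(sex, offs) {
    profs <- vapply(seq_len(n_per_sex), function(i) {
      truth <- sample_fly(child_seed(seed, offs + i), sex = sex)
      cfg <- render_config(n_frames = n_frames,
                           seed = child_seed(seed, offs + 5000 + i))
      seq <- render_sequence(truth, cfg)
      st <- align_sequence(seq, seq_len(n_frames))
      proj <- percentile_projection(st, q = config$body$percentile)
      mask <- binarize_and_close(proj, config$body$threshold,
                                 config$body$closing_radius,
                                 config$body$min_area)
      segs <- watershed_segments(mask, config$body$min_peak_separation)
      bm <- fit_segment_templates(segs)
      bright <- select_brightest_red_frame(st, bm)
      abdominal_profile(st$red_frames[[bright]], bm$labels == 3,
                        n_samples = config$sex$n_samples)$values
    }, numeric(config$sex$n_samples))
    rowMeans(profs)
  }
  list(male = one_sex("male", 0), female = one_sex("female", 10000),
       positions = seq(0, 1, length.out = config$sex$n_samples))
}
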