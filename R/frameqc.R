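# Per-frame validity checks mirroring the real-time validation step of the
# acquisition system, and the >= 3-valid-frames sequence decision.

#' Focus check
#'
#' A frame is in focus when the variance of the 4-neighbour Laplacian inside
#' the fly bounding box reaches `threshold`. The frame is pre-smoothed with a
#' 1 px Gaussian so that sensor noise does not dominate the metric.
#'
#' @param frame grayscale matrix (blue channel).
#' @param threshold minimum Laplacian variance.
#' @param mask optional foreground mask restricting the bounding box; with no
#'   foreground the metric is 0 and the check fails.
#' @return list `(ok, metric)`.
#' @export
check_focus <- function(frame, threshold, mask = NULL) {
  roi <- frame
  if (!is.null(mask)) {
    if (!any(mask)) return(list(ok = FALSE, metric = 0))
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    rows <- clamp(c(rows[1] - 3, rows[2] + 3), 1, nrow(frame))
    cols <- clamp(c(cols[1] - 3, cols[2] + 3), 1, ncol(frame))
    roi <- frame[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  }
  if (stats::sd(roi) < 1e-12) return(list(ok = FALSE, metric = 0))
  sm <- from_ebimage(EBImage::gblur(as_ebimage(roi), sigma = 1))
  metric <- laplacian_variance(sm)
  list(ok = metric >= threshold, metric = metric)
}

#' Border-clearance check
#'
#' True iff no foreground pixel lies within `margin` px of any image border.
#' An empty mask fails (no fly detected).
#'
#' @param mask logical foreground mask (body + wings + legs).
#' @param margin border width in px (default 2).
#' @export
check_border_clearance <- function(mask, margin = 2) {
  if (!any(mask)) return(FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- max(1L, as.integer(margin))
  !(any(mask[seq_len(m), ]) || any(mask[(nr - m + 1):nr, ]) ||
      any(mask[, seq_len(m)]) || any(mask[, (nc - m + 1):nc]))
}

#' Wing-reflection check
#'
#' True iff the fraction of saturated pixels in the wing region of the red
#' channel stays below `max_fraction`.
#'
#' @param red_frame red-channel matrix.
#' @param wing_region logical mask of the wing area (foreground minus body
#'   core).
#' @param saturation_level luminance treated as saturated (default 250/255).
#' @param max_fraction maximum tolerated saturated fraction (default 0.5%).
#' @return list `(ok, metric)` where metric is the saturated fraction.
#' @export
check_reflections <- function(red_frame, wing_region,
                              saturation_level = 250 / 255,
                              max_fraction = 0.005) {
  n <- sum(wing_region)
  if (n == 0) return(list(ok = TRUE, metric = 0))
  frac <- sum(red_frame[wing_region] >= saturation_level) / n
  list(ok = frac < max_fraction, metric = frac)
}

#' Orientation and tunnel-alignment checks
#'
#' `alignment_ok` iff the angle between the silhouette's second-moment major
#' axis and the tunnel (vertical) axis is at most `max_angle_deg`.
#' `orientation_ok` iff the wing silhouette area outside the body core is at
#' least `min_wing_ratio` of the body-core area: a dorsal view with both
#' wings facing the camera exposes the wing blades beside the body.
#'
#' @param mask logical foreground mask.
#' @param max_angle_deg maximum axis deviation (default 10).
#' @param body_core logical mask of the body without wings/legs; computed by
#'   [validate_frame()] from the strongly absorbing silhouette.
#' @param min_wing_ratio minimum wing-to-body area ratio (default 0.3).
#' @param min_area degenerate-mask guard; below it both checks fail.
#' @return list `(orientation_ok, alignment_ok, angle_deg, wing_ratio)`.
#' @export
check_orientation_and_alignment <- function(mask, max_angle_deg = 10,
                                            body_core = NULL,
                                            min_wing_ratio = 0.3,
                                            min_area = 200) {
  if (sum(mask) < min_area) {
    return(list(orientation_ok = FALSE, alignment_ok = FALSE,
                angle_deg = NA_real_, wing_ratio = NA_real_))
  }
  # the axis comes from the elongated body core when available: the full
  # silhouette with spread wings is nearly isotropic and its principal
  # direction is unstable
  mm <- mass_moments((if (!is.null(body_core) && sum(body_core) >= min_area)
    body_core else mask) * 1)
  angle <- abs(mm$theta) * 180 / pi
  alignment_ok <- angle <= max_angle_deg
  if (is.null(body_core)) body_core <- mask
  core_area <- sum(body_core)
  if (core_area < min_area) {
    return(list(orientation_ok = FALSE, alignment_ok = alignment_ok,
                angle_deg = angle, wing_ratio = NA_real_))
  }
  dil <- from_ebimage(EBImage::dilate(as_ebimage(body_core * 1),
                                      EBImage::makeBrush(5, "disc"))) > 0.5
  wing_ratio <- sum(mask & !dil) / core_area
  list(orientation_ok = wing_ratio >= min_wing_ratio,
       alignment_ok = alignment_ok,
       angle_deg = angle, wing_ratio = wing_ratio)
}

#' Bilateral-symmetry check
#'
#' Rotates the silhouette so its major axis is vertical, mirrors it across
#' the axis through the centroid, and accepts when the intersection-over-
#' union of mask and mirror reaches `min_iou`.
#'
#' @param mask logical foreground mask.
#' @param min_iou acceptance threshold (default 0.85).
#' @param body_core optional body-only mask whose (stable) principal axis
#'   defines the mirror line; by default the axis of `mask` itself.
#' @return list `(ok, iou)`.
#' @export
check_symmetry <- function(mask, min_iou = 0.85, body_core = NULL) {
  if (!any(mask)) return(list(ok = FALSE, iou = 0))
  mm <- mass_moments((if (!is.null(body_core) && any(body_core)) body_core
                      else mask) * 1)
  up <- warp_rigid(mask * 1, theta = -mm$theta, in_center = mm$centroid,
                   out_center = mm$centroid, fill = 0) > 0.5
  cx <- mm$centroid[1]
  nc <- ncol(up)
  refl_cols <- round(2 * cx - seq_len(nc))
  ok_cols <- refl_cols >= 1 & refl_cols <= nc
  mirrored <- matrix(FALSE, nrow(up), nc)
  mirrored[, ok_cols] <- up[, refl_cols[ok_cols]]
  iou <- sum(up & mirrored) / sum(up | mirrored)
  list(ok = iou >= min_iou, iou = iou)
}

#' Validate one frame pair
#'
#' Runs all six frame-quality criteria (focus, border clearance, wing
#' reflections, dorsal wing exposure, tunnel alignment, bilateral symmetry);
#' the frame is valid iff every criterion passes.
#'
#' @param frame list with `blue` and `red` matrices (registered channels).
#' @param background list with `blue` (and optionally `red`) background
#'   matrices.
#' @param config an [fw_config()].
#' @return object of class `frame_qc`: logical flags `focus_ok`, `border_ok`,
#'   `reflection_ok`, `orientation_ok`, `alignment_ok`, `symmetry_ok`,
#'   `valid`, plus a `metrics` list backing each flag.
#' @export
validate_frame <- function(frame, background, config = fw_config()) {
  if (!identical(dim(frame$blue), dim(frame$red)) ||
      !identical(dim(frame$blue), dim(background$blue))) {
    stop("channel/background shape mismatch")
  }
  qc <- config$qc
  diff <- background$blue - frame$blue
  fg <- diff > qc$foreground_delta
  border_ok <- check_border_clearance(fg, qc$border_margin)
  if (!any(fg)) {
    flags <- c(focus_ok = FALSE, border_ok = FALSE, reflection_ok = TRUE,
               orientation_ok = FALSE, alignment_ok = FALSE,
               symmetry_ok = FALSE)
    return(structure(c(as.list(flags), list(
      valid = FALSE,
      metrics = list(focus = 0, reflection_fraction = 0,
                     angle_deg = NA_real_, wing_ratio = NA_real_,
                     symmetry_iou = 0))), class = "frame_qc"))
  }
  # all remaining checks run on the fly bounding box (plus margin)
  rows <- clamp(range(which(rowSums(fg) > 0)) + c(-8, 8), 1, nrow(fg))
  cols <- clamp(range(which(colSums(fg) > 0)) + c(-8, 8), 1, ncol(fg))
  ri <- rows[1]:rows[2]; ci <- cols[1]:cols[2]
  fg_c <- fg[ri, ci, drop = FALSE]
  strong <- diff[ri, ci, drop = FALSE] > qc$body_delta
  core <- from_ebimage(EBImage::opening(as_ebimage(strong * 1),
                                        EBImage::makeBrush(7, "disc"))) > 0.5
  focus <- check_focus(frame$blue[ri, ci, drop = FALSE], qc$focus_threshold,
                       mask = fg_c)
  dil <- from_ebimage(EBImage::dilate(as_ebimage(core * 1),
                                      EBImage::makeBrush(5, "disc"))) > 0.5
  wing_region <- fg_c & !dil
  refl <- check_reflections(frame$red[ri, ci, drop = FALSE], wing_region,
                            qc$saturation_level,
                            qc$max_reflection_fraction)
  ori <- check_orientation_and_alignment(fg_c, qc$max_axis_angle_deg,
                                         body_core = core,
                                         min_wing_ratio = qc$min_wing_ratio)
  sym <- check_symmetry(fg_c, qc$min_symmetry_iou, body_core = core)
  flags <- c(focus_ok = focus$ok, border_ok = border_ok,
             reflection_ok = refl$ok, orientation_ok = ori$orientation_ok,
             alignment_ok = ori$alignment_ok, symmetry_ok = sym$ok)
  structure(c(as.list(flags), list(
    valid = all(flags),
    metrics = list(focus = focus$metric, reflection_fraction = refl$metric,
                   angle_deg = ori$angle_deg, wing_ratio = ori$wing_ratio,
                   symmetry_iou = sym$iou))),
    class = "frame_qc")
}

#' QC a whole sequence
#'
#' @param seq a `frame_sequence`.
#' @param config an [fw_config()].
#' @return list of `frame_qc`, one per frame.
#' @export
qc_sequence <- function(seq, config = fw_config()) {
  lapply(seq$frames, validate_frame, background = seq$background,
         config = config)
}

#' Sequence accept/reject decision
#'
#' A sequence is accepted iff it contains at least `min_valid_frames`
#' (default 3) valid frames.
#'
#' @param results list of `frame_qc` results.
#' @param min_valid_frames acceptance minimum (default 3).
#' @return object of class `sequence_decision`: `n_valid`, `accepted`,
#'   `valid_frame_indices`.
#' @export
accept_sequence <- function(results, min_valid_frames = 3) {
  valid <- vapply(results, function(r) isTRUE(r$valid), logical(1))
  structure(list(n_valid = sum(valid),
                 accepted = sum(valid) >= min_valid_frames,
                 valid_frame_indices = which(valid)),
            class = "sequence_decision")
}

#' @export
print.sequence_decision <- function(x, ...) {
  cat(sprintf("<sequence_decision> %s (%d valid frame%s: %s)\n",
              if (x$accepted) "ACCEPTED" else "REJECTED", x$n_valid,
              if (x$n_valid == 1) "" else "s",
              paste(x$valid_frame_indices, collapse = ", ")))
  invisible(x)
}

#' Per-sequence QC report table
#'
#' @param results list of `frame_qc`.
#' @param fly_id identifier written into the first column.
#' @return data.frame with one row per frame: flags and `valid`.
#' @export
qc_report <- function(results, fly_id = NA) {
  do.call(rbind, lapply(seq_along(results), function(k) {
    r <- results[[k]]
    data.frame(fly_id = fly_id, frame = k, focus_ok = r$focus_ok,
               border_ok = r$border_ok, reflection_ok = r$reflection_ok,
               orientation_ok = r$orientation_ok,
               alignment_ok = r$alignment_ok, symmetry_ok = r$symmetry_ok,
               valid = r$valid)
  }))
}
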