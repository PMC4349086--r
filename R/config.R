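#' Pipeline configuration
#'
#' Builds the full configuration for the analysis pipeline. All thresholds of
#' every stage live in this one structure so that a batch run is reproducible
#' from the config file alone. Values are given on the \[0, 1\] luminance
#' scale (8-bit level / 255) and in pixels.
#'
#' @param ... named overrides. Nested blocks are merged key-by-key, e.g.
#'   `fw_config(qc = list(focus_threshold = 1e-3))`. Unknown keys are an
#'   error, so typos cannot silently fall back to defaults.
#' @return a nested list of class `fw_config`.
#'
#' @section Blocks:
#' \describe{
#'   \item{qc}{frame-validity thresholds: `min_valid_frames` (sequence
#'     acceptance needs at least this many valid frames, default 3),
#'     `focus_threshold` (variance of the Laplacian inside the fly bounding
#'     box), `border_margin` (px), `saturation_level` and
#'     `max_reflection_fraction` (wing-region saturated-pixel rule),
#'     `max_axis_angle_deg` (tunnel alignment), `min_wing_ratio`
#'     (wing-to-body area, dorsal-view check), `min_symmetry_iou`
#'     (mirror IoU about the body axis), `foreground_delta` and
#'     `body_delta` (background-subtraction thresholds).}
#'   \item{body}{segmentation: `percentile` for the temporal projection
#'     (default 95), `closing_radius` (structuring-element radius used to
#'     strip wing veins and bristles), `min_area`, `threshold`
#'     (`"otsu"` or a number).}
#'   \item{sex}{`tau_comb`, `tau_lum` decision thresholds,
#'     `eccentricity_max` for sex-comb candidate blobs, `comb_threshold`
#'     (dark-spot level in the red channel), `comb_area_range`,
#'     `comb_area_ref`, `n_samples` (luminance-profile resampling length).}
#'   \item{head}{`ocelli_min_ncc` (template-match acceptance),
#'     `edge_rel_threshold` (eye-edge derivative peak, relative to the
#'     strongest peak), `profile_sigma` (Gaussian derivative smoothing, px),
#'     `roi_margin` (px).}
#'   \item{wing}{`clahe_blocks`, `clahe_clip`, `ratio_threshold`
#'     (structure-to-local-background luminance ratio), `local_sigma`
#'     (local background blur, px), `min_object_px`, `max_iter`, `tol_px`
#'     (spline refit convergence).}
#'   \item{select}{`criterion` (relative wing size formula, default
#'     `"wa/sw^2"`), `capacity` (storage wells, soft limit).}
#'   \item{mm_per_px}{pixel calibration used only when reporting mm.}
#' }
#' @export
fw_config <- function(...) {
  defaults <- list(
    mm_per_px = 0.02,
    qc = list(
      min_valid_frames = 3,
      focus_threshold = NULL,      # set below; calibrated on the renderer
      border_margin = 2,
      saturation_level = 250 / 255,
      max_reflection_fraction = 0.005,
      max_axis_angle_deg = 10,
      min_wing_ratio = 0.3,
      min_symmetry_iou = 0.85,
      foreground_delta = 0.08,
      body_delta = 0.35
    ),
    body = list(
      percentile = 95,
      closing_radius = 3,
      min_area = 500,
      threshold = "otsu",
      min_peak_separation = 25
    ),
    sex = list(
      tau_comb = 0.3,
      tau_lum = 0.15,
      eccentricity_max = 0.95,
      comb_threshold = 0.16,
      comb_area_range = c(3, 80),
      comb_area_ref = 8,
      n_samples = 100
    ),
    head = list(
      ocelli_min_ncc = 0.5,
      edge_rel_threshold = 0.4,
      profile_sigma = 1,
      roi_margin = 5
    ),
    wing = list(
      clahe_blocks = 8,
      clahe_clip = 2,
      ratio_threshold = 0.78,
      local_sigma = 5,
      min_object_px = 30,
      max_iter = 20,
      tol_px = 0.1
    ),
    select = list(
      criterion = "wa/sw^2",
      capacity = 182
    )
  )
  # focus threshold: midway (log scale) between a sharp and a sigma-4
  # defocused render of the default fly; frozen here as a constant.
  defaults$qc$focus_threshold <- 2e-4
  cfg <- merge_config(defaults, list(...), path = "")
  class(cfg) <- "fw_config"
  cfg
}

merge_config <- function(base, override, path = "") {
  if (length(override) == 0) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) {
    stop("config overrides must be named (at '", path, "')")
  }
  for (nm in nms) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) stop("unknown config key: '", key, "'")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) stop("config key '", key, "' must be a block")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file holds only overrides of [fw_config()] defaults; reading it
#' validates every key, and a config written by [write_config()] reads back
#' losslessly.
#'
#' @param path YAML file path.
#' @return `read_config()`: an `fw_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(fw_config, vals)
}

#' @rdname read_config
#' @param cfg an `fw_config` object.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}
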