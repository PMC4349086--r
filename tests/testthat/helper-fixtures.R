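# Shared fixtures, computed once per test run. Each fixture is a rendered
# synthetic fly taken through the body-segmentation pipeline; tests reuse
# them instead of re-rendering.

fw_fixture_env <- new.env(parent = emptyenv())

fw_fixture <- function(name) {
  if (!is.null(fw_fixture_env[[name]])) return(fw_fixture_env[[name]])
  fx <- switch(name,
    female = build_pipeline_fixture(seed = 3, sex = "female", render_seed = 503),
    male = build_pipeline_fixture(seed = 52, sex = "male", render_seed = 952),
    stop("unknown fixture ", name))
  fw_fixture_env[[name]] <- fx
  fx
}

build_pipeline_fixture <- function(seed, sex, render_seed) {
  truth <- sample_fly(seed, sex = sex)
  cfg <- render_config(seed = render_seed)
  seq <- render_sequence(truth, cfg)
  qc <- qc_sequence(seq)
  dec <- accept_sequence(qc)
  stack <- align_sequence(seq, dec$valid_frame_indices)
  proj <- percentile_projection(stack)
  mask <- binarize_and_close(proj)
  segs <- watershed_segments(mask, red_frame = stack$red_frames[[1]])
  bm <- fit_segment_templates(segs)
  list(truth = truth, cfg = cfg, seq = seq, qc = qc, dec = dec,
       stack = stack, proj = proj, mask = mask, segs = segs, bm = bm)
}

# Map a body-frame point of the fixture's fly into the aligned-stack frame
# of a given aligned frame index (for comparing pipeline output with the
# generator's ground-truth geometry).
map_body_point <- function(fx, p, frame = 1) {
  k <- fx$stack$frame_indices[frame]
  tr <- fx$stack$transforms[[frame]]
  th_k <- fx$seq$poses$thetas[k]
  c_k <- fx$seq$poses$centers[k, ]
  pi_full <- c(cos(th_k) * p[1] - sin(th_k) * p[2],
               sin(th_k) * p[1] + cos(th_k) * p[2]) + c_k
  off <- fx$stack$crop_offset          # (row0, col0)
  pi_crop <- pi_full - c(off[2], off[1])
  d <- pi_crop - tr$centroid
  th_a <- tr$theta
  pa <- c(cos(th_a) * d[1] + sin(th_a) * d[2],
          -sin(th_a) * d[1] + cos(th_a) * d[2]) + fx$stack$center
  if (tr$flip) {
    pa <- c(ncol(fx$stack$frames[[1]]) + 1 - pa[1],
            nrow(fx$stack$frames[[1]]) + 1 - pa[2])
  }
  pa
}

# Rasterize a stroked polyline into a logical matrix (test oracle geometry).
rasterize_strokes <- function(polylines, nrow, ncol, width = 1.8) {
  X <- rep(seq_len(ncol), each = nrow)
  Y <- rep(seq_len(nrow), times = ncol)
  a <- numeric(length(X))
  for (pts in polylines) {
    a <- pmax(a, flywalk:::stroke_alpha(X, Y, pts, width))
  }
  matrix(a, nrow, ncol) > 0.5
}

# Build an ellipse mask (test geometry helper): semi-axis `a` along rows.
ellipse_mask <- function(nrow, ncol, center, a, b, theta = 0) {
  X <- rep(seq_len(ncol), each = nrow) - center[1]
  Y <- rep(seq_len(nrow), times = ncol) - center[2]
  xr <- cos(theta) * X + sin(theta) * Y
  yr <- -sin(theta) * X + cos(theta) * Y
  matrix((xr / b)^2 + (yr / a)^2 <= 1, nrow, ncol)
}
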