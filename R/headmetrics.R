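# Interocular distance: brightest red frame, head ROI from the body model,
# ocelli localisation by normalized cross-correlation template matching,
# then eye edges from the luminance derivative along the posterior-ocelli
# line.

#' Select the brightest red frame
#'
#' Index of the aligned frame maximizing mean red luminance within the fly
#' mask (the whole frame when no body model is supplied). Ties go to the
#' first frame.
#'
#' @param stack an `aligned_stack` with red frames, or a list of matrices.
#' @param body_model optional `body_model`; restricts the mean to the body.
#' @return frame index.
#' @export
select_brightest_red_frame <- function(stack, body_model = NULL) {
  reds <- if (inherits(stack, "aligned_stack")) stack$red_frames else stack
  stopifnot(length(reds) >= 1)
  mask <- if (!is.null(body_model)) body_model$labels > 0 else NULL
  means <- vapply(reds, function(fr) {
    if (is.null(mask)) mean(fr) else mean(fr[mask])
  }, numeric(1))
  which.max(means)          # first-wins tie-break
}

#' Head region of interest
#'
#' Bounding box of the head segment, dilated by `margin` px and clipped to
#' the frame.
#'
#' @param frame aligned frame matrix (red channel).
#' @param body_model a `body_model` with a head segment.
#' @param margin dilation in px (default 5).
#' @return list `(rows, cols, image)`.
#' @export
locate_head <- function(frame, body_model, margin = 5) {
  if (is.null(body_model$labels) || !any(body_model$labels == 1)) {
    stop("body model has no head segment")
  }
  head_mask <- body_model$labels == 1
  rows <- range(which(rowSums(head_mask) > 0))
  cols <- range(which(colSums(head_mask) > 0))
  rows <- clamp(c(rows[1] - margin, rows[2] + margin), 1, nrow(frame))
  cols <- clamp(c(cols[1] - margin, cols[2] + margin), 1, ncol(frame))
  list(rows = rows[1]:rows[2], cols = cols[1]:cols[2],
       image = frame[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
}

#' Default ocelli template
#'
#' Three Gaussian bright dots in the ocellar-triangle arrangement the
#' renderer uses: a posterior pair `sep` px apart and an anterior dot
#' `anterior_offset` px forward of their midpoint.
#'
#' @param sep posterior pair separation (px).
#' @param anterior_offset anterior dot offset (px).
#' @param sigma dot width (px).
#' @param size template side length (odd).
#' @return list `(image, posterior, sep)` with posterior dot centres in
#'   template coordinates.
#' @export
ocelli_template <- function(sep = 11, anterior_offset = 6, sigma = 1.4,
                            size = 17) {
  stopifnot(size %% 2 == 1)
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size)
  y <- matrix(rep(seq_len(size), times = size), size)
  dots <- rbind(c(c0 - sep / 2, c0 + 2), c(c0 + sep / 2, c0 + 2),
                c(c0, c0 + 2 - anterior_offset))
  img <- matrix(0, size, size)
  for (i in 1:3) {
    img <- img + exp(-((x - dots[i, 1])^2 + (y - dots[i, 2])^2) /
                       (2 * sigma^2))
  }
  list(image = img, posterior = dots[1:2, ], sep = sep)
}

# Normalized cross-correlation of template over image (valid region),
# returning the NCC matrix indexed by the template-centre position.
ncc_match <- function(image, template) {
  th <- nrow(template); tw <- ncol(template)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < th || nc < tw) stop("ROI smaller than template")
  tz <- template - mean(template)
  tnorm <- sqrt(sum(tz^2))
  # filter2 performs convolution; flip the kernel to get correlation
  tz <- tz[nrow(tz):1, ncol(tz):1]
  ones <- matrix(1, th, tw)
  # sliding sums via FFT-backed filter2 on a padded copy
  s1 <- from_ebimage(EBImage::filter2(as_ebimage(image), as_ebimage(ones),
                                      boundary = "replicate"))
  s2 <- from_ebimage(EBImage::filter2(as_ebimage(image^2), as_ebimage(ones),
                                      boundary = "replicate"))
  num <- from_ebimage(EBImage::filter2(as_ebimage(image), as_ebimage(tz),
                                       boundary = "replicate"))
  npx <- th * tw
  denom <- sqrt(pmax(s2 - s1^2 / npx, 1e-12)) * tnorm
  ncc <- num / denom
  # valid centre positions only
  rh <- (th - 1) %/% 2; cw <- (tw - 1) %/% 2
  valid <- matrix(-Inf, nr, nc)
  valid[(rh + 1):(nr - rh), (cw + 1):(nc - cw)] <-
    ncc[(rh + 1):(nr - rh), (cw + 1):(nc - cw)]
  valid
}

# Quadratic sub-pixel interpolation of a peak at integer position (r, c).
subpixel_peak <- function(m, r, c) {
  dr <- dc <- 0
  if (r > 1 && r < nrow(m)) {
    a <- m[r - 1, c]; b <- m[r, c]; d <- m[r + 1, c]
    den <- a - 2 * b + d
    if (abs(den) > 1e-12) dr <- clamp(0.5 * (a - d) / den, -0.5, 0.5)
  }
  if (c > 1 && c < ncol(m)) {
    a <- m[r, c - 1]; b <- m[r, c]; d <- m[r, c + 1]
    den <- a - 2 * b + d
    if (abs(den) > 1e-12) dc <- clamp(0.5 * (a - d) / den, -0.5, 0.5)
  }
  c(r + dr, c + dc)
}

#' Locate the posterior ocelli by template matching
#'
#' Normalized cross-correlation of the ocelli template over the head ROI;
#' the peak (sub-pixel, quadratic interpolation) gives the triangle pose,
#' and each posterior dot centre is then refined by a local intensity
#' centroid in a small window.
#'
#' @param head_roi list from [locate_head()] (or a plain matrix).
#' @param template an [ocelli_template()].
#' @param min_ncc minimum peak correlation; below it the ocelli are declared
#'   not found.
#' @return list `(posterior, ncc)`: posterior dot centres as an (x, y) 2 x 2
#'   matrix in frame coordinates (or ROI coordinates for a plain matrix).
#' @export
match_ocelli <- function(head_roi, template = ocelli_template(),
                         min_ncc = 0.5) {
  roi <- if (is.list(head_roi)) head_roi$image else head_roi
  off <- if (is.list(head_roi)) {
    c(head_roi$cols[1] - 1, head_roi$rows[1] - 1)
  } else c(0, 0)
  ncc <- ncc_match(roi, template$image)
  peak <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  if (ncc[peak[1], peak[2]] < min_ncc) stop("ocelli not found")
  sp <- subpixel_peak(ncc, peak[1], peak[2])
  c0 <- (nrow(template$image) + 1) / 2
  # posterior dots relative to the template centre (x, y)
  rel <- template$posterior - c0
  centers <- cbind(sp[2] + rel[, 1], sp[1] + rel[, 2])
  # refine each dot by local intensity centroid
  for (i in 1:2) {
    cx <- round(centers[i, 1]); cy <- round(centers[i, 2])
    win <- 3
    rr <- clamp(c(cy - win, cy + win), 1, nrow(roi))
    cc <- clamp(c(cx - win, cx + win), 1, ncol(roi))
    sub <- roi[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    w <- pmax(sub - min(sub), 0)
    if (sum(w) > 0) {
      xs <- cc[1]:cc[2]; ys <- rr[1]:rr[2]
      centers[i, 1] <- sum(colSums(w) * xs) / sum(w)
      centers[i, 2] <- sum(rowSums(w) * ys) / sum(w)
    }
  }
  list(posterior = sweep(centers, 2, -off), ncc = ncc[peak[1], peak[2]])
}

#' Eye edges and interocular distance
#'
#' Samples the luminance along the line through both posterior ocelli,
#' extended to both sides, smooths it with a Gaussian of `sigma` px,
#' takes the central finite-difference derivative, and places the eye edges
#' at the outermost derivative-magnitude peaks exceeding
#' `rel_threshold x` (strongest peak) on each side of the ocelli midpoint.
#' The interocular distance is the distance between the two edges.
#'
#' @param frame aligned red-channel matrix.
#' @param ocelli_pair 2 x 2 matrix of posterior ocelli centres (x, y).
#' @param half_length scan half-length in px (default 60).
#' @param sigma derivative pre-smoothing (px).
#' @param rel_threshold relative peak acceptance threshold.
#' @param mm_per_px calibration for the mm output.
#' @return object of class `head_measurement`: `ocelli_posterior`,
#'   `eye_edges` (2 x 2, x/y), `iod_px`, `iod_mm`, `profile`.
#' @export
eye_edges_and_iod <- function(frame, ocelli_pair, half_length = 60,
                              sigma = 1, rel_threshold = 0.4,
                              mm_per_px = NA) {
  mid <- colMeans(ocelli_pair)
  dirv <- ocelli_pair[2, ] - ocelli_pair[1, ]
  len <- sqrt(sum(dirv^2))
  if (len < 1e-9) stop("degenerate ocelli pair")
  dirv <- dirv / len
  s <- seq(-half_length, half_length, by = 0.5)
  xs <- mid[1] + s * dirv[1]
  ys <- mid[2] + s * dirv[2]
  prof <- bilinear_sample(frame, xs, ys, fill = NA)
  ok <- !is.na(prof)
  s <- s[ok]; prof <- prof[ok]
  # Gaussian smoothing (sample spacing 0.5 px)
  ksig <- sigma / 0.5
  kx <- seq(-ceiling(3 * ksig), ceiling(3 * ksig))
  kern <- exp(-kx^2 / (2 * ksig^2)); kern <- kern / sum(kern)
  sm <- stats::filter(prof, kern, sides = 2)
  deriv <- c(NA, diff(sm, lag = 2) / (2 * 0.5), NA)
  mag <- abs(deriv)
  mag[is.na(mag)] <- 0
  # local maxima of |derivative|
  n <- length(mag)
  is_peak <- c(FALSE, mag[2:(n - 1)] >= mag[1:(n - 2)] &
                 mag[2:(n - 1)] >= mag[3:n], FALSE) & mag > 0
  thr <- rel_threshold * max(mag)
  cand <- which(is_peak & mag >= thr)
  left <- cand[s[cand] < 0]
  right <- cand[s[cand] > 0]
  if (length(left) == 0 || length(right) == 0) stop("eye edges not found")
  iL <- left[which.min(s[left])]      # outermost on each side
  iR <- right[which.max(s[right])]
  # sub-pixel refinement of each derivative peak
  refine <- function(i) {
    if (i <= 1 || i >= n) return(s[i])
    a <- mag[i - 1]; b <- mag[i]; d <- mag[i + 1]
    den <- a - 2 * b + d
    ds <- if (abs(den) > 1e-12) clamp(0.5 * (a - d) / den, -0.5, 0.5) else 0
    s[i] + ds * 0.5
  }
  sL <- refine(iL); sR <- refine(iR)
  iod <- sR - sL
  edges <- rbind(mid + sL * dirv, mid + sR * dirv)
  structure(list(ocelli_posterior = ocelli_pair, eye_edges = edges,
                 scan_line = list(point = mid, direction = dirv),
                 iod_px = iod, iod_mm = iod * mm_per_px,
                 profile = list(s = s, luminance = prof,
                                derivative = deriv)),
            class = "head_measurement")
}

#' @export
print.head_measurement <- function(x, ...) {
  cat(sprintf("<head_measurement> IOD = %.2f px (%.3f mm)\n",
              x$iod_px, x$iod_mm))
  invisible(x)
}

#' Measure interocular distance for an aligned sequence
#'
#' Brightest red frame, head ROI, ocelli template match, eye-edge scan.
#'
#' @param stack an `aligned_stack` with red frames.
#' @param body_model a `body_model`.
#' @param config an [fw_config()].
#' @param template ocelli template (default [ocelli_template()]).
#' @return a `head_measurement`.
#' @export
measure_head <- function(stack, body_model, config = fw_config(),
                         template = ocelli_template()) {
  hd <- config$head
  bright <- select_brightest_red_frame(stack, body_model)
  frame <- stack$red_frames[[bright]]
  roi <- locate_head(frame, body_model, margin = hd$roi_margin)
  oc <- match_ocelli(roi, template, min_ncc = hd$ocelli_min_ncc)
  eye_edges_and_iod(frame, oc$posterior,
                    half_length = max(40, 2 * body_model$head$width),
                    sigma = hd$profile_sigma,
                    rel_threshold = hd$edge_rel_threshold,
                    mm_per_px = stack$mm_per_px %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
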