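# Body segmentation: background subtraction and complement, central-moment
# alignment of the valid frames into a stack, temporal percentile projection
# to delete the moving legs, threshold + morphological cleanup, and
# marker-controlled watershed into head / thorax / abdomen.

#' Background subtraction and complement
#'
#' Subtracting a frame from the background gives a bright fly on a dark
#' background; the complement inverts this to the dark-fly-on-bright
#' convention used by the alignment and projection steps. Output is
#' `1 - clamp(background - frame, 0, 1)`: background pixels sit at ~1.
#'
#' @param frame_blue blue-channel matrix.
#' @param background blue-channel background matrix of the same shape.
#' @return complemented difference image in \[0, 1\].
#' @export
subtract_and_complement <- function(frame_blue, background) {
  if (!identical(dim(frame_blue), dim(background))) stop("shape mismatch")
  1 - clamp(background - frame_blue, 0, 1)
}

#' Align frames by central image moments
#'
#' For each complemented frame the centroid and second-moment major axis of
#' the dark mass are computed; the frame is translated so the centroid lands
#' on the stack centre and rotated so the major axis is vertical. The 180
#' degree ambiguity is resolved by the convention that the widest body
#' section (the abdomen) lies below the centroid (larger row index);
#' frames are flipped as needed. Moments are computed on the strongly
#' absorbing body silhouette only, so the translucent wings and the moving
#' legs barely perturb the pose estimate.
#'
#' @param images list of complemented images (dark fly on bright field).
#' @param red_images optional list of matching red-channel frames warped with
#'   the same per-frame transform (registered channels).
#' @param mass_floor darkness below this is treated as background noise.
#' @return object of class `aligned_stack`: `frames` (aligned complemented
#'   images), `red_frames` (or `NULL`), `transforms` (per-frame centroid,
#'   angle and flip actually applied), `center`.
#' @export
moments_align <- function(images, red_images = NULL, mass_floor = 0.45) {
  stopifnot(length(images) >= 1)
  nr <- nrow(images[[1]]); nc <- ncol(images[[1]])
  center <- c((nc + 1) / 2, (nr + 1) / 2)
  frames <- list(); reds <- list(); transforms <- list()
  scores <- numeric(0)
  for (k in seq_along(images)) {
    img <- images[[k]]
    dark <- 1 - img
    strong <- dark > mass_floor
    # body silhouette only: drop the thin legs so their frame-to-frame
    # movement cannot jitter the pose estimate
    body <- from_ebimage(EBImage::opening(as_ebimage(strong * 1),
                                          EBImage::makeBrush(5, "disc"))) > 0.5
    if (!any(body)) body <- strong
    w <- dark * body
    mm <- mass_moments(w)
    if (is.null(mm) || mm$m00 < 1) {
      warning("zero-mass frame ", k, " skipped")
      next
    }
    theta <- mm$theta
    al <- warp_rigid(img, theta = theta, in_center = mm$centroid,
                     out_center = center, fill = 1)
    # flip score: positive when the widest leg-free body section (the
    # abdomen) already lies below the centroid
    wa <- (1 - al) > mass_floor
    wa <- from_ebimage(EBImage::opening(as_ebimage(wa * 1),
                                        EBImage::makeBrush(5, "disc"))) > 0.5
    widths <- rowSums(wa)
    widths <- stats::filter(widths, rep(1 / 7, 7), sides = 2)
    widths[is.na(widths)] <- 0
    scores <- c(scores, which.max(widths) - center[2])
    frames[[length(frames) + 1]] <- al
    if (!is.null(red_images)) {
      rfill <- stats::median(red_images[[k]][c(1, nr), ])
      rd <- warp_rigid(red_images[[k]], theta = theta,
                       in_center = mm$centroid, out_center = center,
                       fill = rfill)
      reds[[length(reds) + 1]] <- rd
    }
    transforms[[length(transforms) + 1]] <-
      list(frame = k, centroid = mm$centroid, theta = theta, flip = FALSE)
  }
  if (length(frames) == 0) stop("no frame with foreground mass")
  # one consensus flip for the whole stack: within one tunnel run the fly
  # keeps its walking direction, so a single 180-degree decision (summed
  # over frames) is far more robust than per-frame votes
  if (sum(scores) < 0) {
    frames <- lapply(frames, function(m) m[nr:1, nc:1])
    reds <- lapply(reds, function(m) m[nr:1, nc:1])
    transforms <- lapply(transforms, function(tr) { tr$flip <- TRUE; tr })
  }
  structure(list(frames = frames,
                 red_frames = if (is.null(red_images)) NULL else reds,
                 transforms = transforms, center = center),
            class = "aligned_stack")
}

#' Temporal percentile projection
#'
#' Per-pixel q-th percentile over the aligned stack (linear-interpolation
#' order statistic, the type-7 convention of [stats::quantile()]). On
#' complemented images the moving legs are dark and transient, so a high
#' percentile restores the bright background underneath them.
#'
#' @param stack an `aligned_stack` or a plain list of same-shape matrices.
#' @param q percentile in \[0, 100\] (default 95).
#' @return projected matrix.
#' @export
percentile_projection <- function(stack, q = 95) {
  frames <- if (inherits(stack, "aligned_stack")) stack$frames else stack
  stopifnot(length(frames) >= 1)
  if (q < 0 || q > 100) stop("q outside [0, 100]")
  n <- length(frames)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (n == 1) return(frames[[1]])
  m <- matrix(unlist(frames, use.names = FALSE), nrow = nr * nc, ncol = n)
  # sort each row (pixel) via a single radix order on (pixel, value)
  v <- as.vector(t(m))                       # frame-major per pixel
  idx <- rep(seq_len(nr * nc), each = n)
  o <- order(idx, v, method = "radix")
  sv <- matrix(v[o], nrow = n)               # column j = sorted values, pixel j
  h <- (n - 1) * q / 100 + 1                 # type-7 position
  lo <- floor(h); hi <- ceiling(h); g <- h - lo
  proj <- if (lo == hi) sv[lo, ] else (1 - g) * sv[lo, ] + g * sv[hi, ]
  matrix(proj, nrow = nr, ncol = nc)
}

#' Threshold the projection and remove thin structures
#'
#' Thresholds the percentile projection (Otsu by default; the fly is dark)
#' and removes structures thinner than twice `selem_radius` - wing veins,
#' bristles and any leg residue - by opening the fly mask with a disc
#' (equivalently, closing the dark-fly image). Small disconnected objects
#' are dropped and only the largest connected component is kept.
#'
#' @param image projection image (dark fly on bright background).
#' @param threshold `"otsu"` or a numeric luminance cut; pixels below it are
#'   fly.
#' @param selem_radius structuring-element radius in px (default 3).
#' @param min_area smallest object kept, px^2.
#' @return logical body mask.
#' @export
binarize_and_close <- function(image, threshold = "otsu", selem_radius = 3,
                               min_area = 500) {
  thr <- if (identical(threshold, "otsu")) {
    # two-stage Otsu: the first split separates the bright background and
    # translucent membrane from the dark structures; the second separates
    # the strongly absorbing body from wing veins / bristles, so thin
    # structures never enter the mask in the first place
    t1 <- EBImage::otsu(as_ebimage(image), range = c(0, 1))
    dark <- image[image < t1]
    if (length(dark) > 50) otsu_vector(dark) else t1
  } else threshold
  mask <- image < thr
  if (!any(mask)) stop("no fly: threshold leaves an empty mask")
  brush <- EBImage::makeBrush(2 * selem_radius + 1, "disc")
  opened <- from_ebimage(EBImage::opening(as_ebimage(mask * 1), brush)) > 0.5
  if (!any(opened)) stop("no fly: mask vanished under morphological cleanup")
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(opened * 1)))
  areas <- tabulate(lab[lab > 0])
  if (max(areas) < min_area) stop("no fly: largest object below min_area")
  lab == which.max(areas)
}

#' Watershed split into head, thorax and abdomen
#'
#' Markers are the three strongest maxima of the distance transform along
#' the (vertical) major axis, found on the per-row maximum-distance profile
#' with a minimum peak separation; the mask is then partitioned by
#' marker-controlled watershed on the negated distance transform (descending
#' flood from the markers, so region boundaries form along the
#' distance-ridge "necks" between the body lobes). Labels are ordered
#' anterior to posterior; the head end is the smaller terminal segment
#' (ties broken towards the ocelli when a red frame is supplied).
#'
#' @param mask logical body mask, single connected component, axis vertical.
#' @param min_peak_separation minimum row distance between markers.
#' @param red_frame optional aligned red frame for the ocelli tie-break.
#' @return object of class `body_segments`: `labels` (1 = head, 2 = thorax,
#'   3 = abdomen), `markers` (row/col of each seed), `head_at_top` (logical).
#' @export
watershed_segments <- function(mask, min_peak_separation = 25,
                               red_frame = NULL) {
  if (!any(mask)) stop("segmentation failed: empty mask")
  # work on the mask bounding box
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  rr <- clamp(rr + c(-2, 2), 1, nrow(mask))
  cc <- clamp(cc + c(-2, 2), 1, ncol(mask))
  sub <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  dist <- from_ebimage(EBImage::distmap(as_ebimage(sub * 1)))
  prof <- apply(dist, 1, max)                      # per-row max distance
  prof_s <- stats::filter(prof, rep(1 / 7, 7), sides = 2)
  prof_s[is.na(prof_s)] <- 0
  peaks <- profile_peaks(as.numeric(prof_s), min_sep = min_peak_separation)
  if (length(peaks) < 3) stop("segmentation failed: fewer than 3 distance maxima")
  peaks <- peaks[order(-prof[peaks])][1:3]         # 3 strongest
  peaks <- sort(peaks)                             # along the axis
  seeds <- matrix(0L, nrow(sub), ncol(sub))
  for (i in 1:3) seeds[peaks[i], which.max(dist[peaks[i], ])] <- i
  labs_sub <- marker_watershed(dist, seeds, sub)
  labs <- matrix(0L, nrow(mask), ncol(mask))
  labs[rr[1]:rr[2], cc[1]:cc[2]] <- labs_sub
  marker_cols <- vapply(peaks, function(p) which.max(dist[p, ]), integer(1)) +
    cc[1] - 1
  peaks <- peaks + rr[1] - 1
  areas <- tabulate(labs[labs > 0], nbins = 3)
  head_at_top <- areas[1] <= areas[3]
  if (!is.null(red_frame)) {
    # ocelli are bright dots: compare peak red luminance of the two
    # terminal segments; the head end carries the brighter maxima
    top_max <- max(red_frame[labs == 1])
    bot_max <- max(red_frame[labs == 3])
    if (abs(areas[1] - areas[3]) / max(areas) < 0.1) {
      head_at_top <- top_max >= bot_max
    }
  }
  if (!head_at_top) labs[labs > 0] <- 4 - labs[labs > 0]  # relabel 3<->1
  structure(list(labels = labs,
                 markers = cbind(row = peaks, col = marker_cols),
                 head_at_top = head_at_top),
            class = "body_segments")
}

# Otsu threshold of a numeric vector (256-bin histogram on [0, 1]).
otsu_vector <- function(x, levels = 256) {
  h <- tabulate(pmin(floor(x * levels) + 1, levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Marker-controlled watershed: descending flood of `height` (here the
# distance transform) from integer-labelled seeds, restricted to `mask`.
# Pixels are claimed level by level from high to low, within a level by
# 4-neighbour shells, so labels meet along the ridge lines of -height.
# Deterministic: fixed neighbour priority (up, down, left, right).
marker_watershed <- function(height, seeds, mask) {
  lab <- seeds
  lab[!mask] <- 0L
  lev <- as.integer(round(height * 2))
  lev[!mask] <- -1L
  nr <- nrow(mask); nc <- ncol(mask)
  shift_lab <- function(l, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- (1 + max(0, dr)):(nr + min(0, dr))
    cs <- (1 + max(0, dc)):(nc + min(0, dc))
    out[rs, cs] <- l[rs - dr, cs - dc]
    out
  }
  grow <- function(lab, assignable) {
    repeat {
      n1 <- shift_lab(lab, 1, 0); n2 <- shift_lab(lab, -1, 0)
      n3 <- shift_lab(lab, 0, 1); n4 <- shift_lab(lab, 0, -1)
      cand <- n1
      cand[cand == 0L] <- n2[cand == 0L]
      cand[cand == 0L] <- n3[cand == 0L]
      cand[cand == 0L] <- n4[cand == 0L]
      frontier <- assignable & lab == 0L & cand > 0L
      if (!any(frontier)) break
      lab[frontier] <- cand[frontier]
    }
    lab
  }
  for (lvl in sort(unique(lev[mask & lev >= 0]), decreasing = TRUE)) {
    lab <- grow(lab, mask & lev == lvl)
  }
  grow(lab, mask)      # mop up pixels isolated from their level's flood
}

# Local maxima of a 1-d profile: maxima over a short window (so that a peak
# just inside a narrow neck is not swallowed by the neighbouring lobe's
# flank), then collapsed so surviving peaks are at least min_sep apart.
profile_peaks <- function(prof, min_sep = 25, window = 10) {
  n <- length(prof)
  w <- min(window, min_sep)
  cand <- which(prof > 0)
  cand <- cand[cand > 1 & cand < n]
  is_peak <- vapply(cand, function(i) {
    lo <- max(1, i - w); hi <- min(n, i + w)
    prof[i] >= max(prof[lo:hi]) && prof[i] > min(prof[lo:hi])
  }, logical(1))
  peaks <- cand[is_peak]
  if (length(peaks) > 1) {
    keep <- c()
    for (p in peaks[order(-prof[peaks])]) {
      if (length(keep) == 0 || all(abs(p - keep) > min_sep)) keep <- c(keep, p)
    }
    peaks <- sort(keep)
  }
  peaks
}

#' Fit segment ellipses and extract dimensions
#'
#' Each labelled segment is summarised by its second-moment ellipse (exact
#' for a filled ellipse): length = 2 x semi-major axis, width = 2 x
#' semi-minor axis, both in px.
#'
#' @param segments a `body_segments` object.
#' @return object of class `body_model`: per-segment list (`head`, `thorax`,
#'   `abdomen`) with `center`, `semi_major`, `semi_minor`, `theta`, `length`,
#'   `width`, `area`, plus the label matrix.
#' @export
fit_segment_templates <- function(segments) {
  stopifnot(inherits(segments, "body_segments"))
  labs <- segments$labels
  props <- region_props(labs)
  if (length(props) != 3) stop("expected 3 segments")
  fits <- lapply(props, function(p) {
    list(center = p$centroid, semi_major = p$semi_major,
         semi_minor = p$semi_minor, theta = p$theta,
         length = 2 * p$semi_major, width = 2 * p$semi_minor,
         area = p$area)
  })
  names(fits) <- c("head", "thorax", "abdomen")
  structure(list(head = fits$head, thorax = fits$thorax,
                 abdomen = fits$abdomen, labels = labs,
                 markers = segments$markers),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  for (s in c("head", "thorax", "abdomen")) {
    cat(sprintf("%-8s length %6.1f px  width %5.1f px  area %6.0f px^2\n",
                s, x[[s]]$length, x[[s]]$width, x[[s]]$area))
  }
  invisible(x)
}

#' Shoulder width from the thorax template scale
#'
#' Shoulder width is extracted indirectly: the thorax template of reference
#' width `reference_width` is scaled to the fitted thorax, and the shoulder
#' width is the reference width times that scale factor. With the default
#' template the scale factor is `fitted thorax width / reference width`, so
#' `sw_px` equals the fitted thorax width; a user template with a different
#' shoulder-to-ellipse ratio changes this proportionally.
#'
#' @param thorax_fit the `thorax` element of a `body_model`.
#' @param template list with `reference_width` (px at scale 1) and
#'   `shoulder_width` (shoulder width of the template at scale 1).
#' @return shoulder width in px.
#' @export
shoulder_width <- function(thorax_fit,
                           template = list(reference_width = 44,
                                           shoulder_width = 44)) {
  scale <- thorax_fit$width / template$reference_width
  template$shoulder_width * scale
}
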