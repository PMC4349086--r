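# Wing morphometrics: two-channel wing-structure extraction, topological
# skeletonization, and iterative B-spline template fitting of the outline
# and longitudinal veins L2-L5, from which wing length (hinge to
# outline-L3), wing width (outline-L2 to outline-L5) and wing area
# (enclosed by the outline) are computed.

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement with clipping (CLAHE), applied to the
#' background-subtracted channel before structure extraction.
#'
#' @param image matrix in \[0, 1\].
#' @param blocks tile grid size per dimension (default 8).
#' @param clip clip limit (default 2).
#' @return enhanced matrix in \[0, 1\].
#' @export
enhance_contrast <- function(image, blocks = 8, clip = 2) {
  if (stats::sd(image) < 1e-12) return(image)
  # pad to a tile-aligned size (replicated edges), equalize, crop back
  nr <- nrow(image); nc <- ncol(image)
  nr2 <- ceiling(nr / blocks) * blocks
  nc2 <- ceiling(nc / blocks) * blocks
  pad <- image[c(seq_len(nr), rep(nr, nr2 - nr)),
               c(seq_len(nc), rep(nc, nc2 - nc)), drop = FALSE]
  out <- from_ebimage(EBImage::clahe(as_ebimage(pad), nx = blocks,
                                     ny = blocks, limit = clip))
  clamp(out[seq_len(nr), seq_len(nc), drop = FALSE], 0, 1)
}

#' Two-channel wing-structure mask
#'
#' Binary mask of the thin wing structures (outline and veins). Off the
#' body, backlighting makes the structures dark against the translucent
#' membrane: they are detected in the blue channel, gated to the wing
#' blades (the membrane's intermediate luminance band). Where wings overlap
#' the body, the transilluminated body acts as the light source and the
#' veins appear as attenuation in the red channel. Both channels are
#' CLAHE-enhanced and thresholded on the ratio of local luminance to a
#' Gaussian-smoothed local background, which is insensitive to the smooth
#' abdominal luminance gradient beneath the wing. Components smaller than
#' `min_object_px` are dropped.
#'
#' @param blue aligned blue-channel image (complemented convention: dark fly
#'   on bright field).
#' @param red aligned red-channel image.
#' @param body_mask logical body mask (without wings/legs).
#' @param config an [fw_config()].
#' @param roi_rows optional row range restricting the red-channel search
#'   (e.g. posterior of the head, to keep eye edges out).
#' @return logical structure mask.
#' @export
wing_mask_two_channel <- function(blue, red, body_mask, config = fw_config(),
                                  roi_rows = NULL) {
  wg <- config$wing
  if (max(blue) - min(blue) < 1e-6 || !any(body_mask)) {
    stop("wing not found: empty frames or body mask")
  }
  blue_e <- enhance_contrast(blue, wg$clahe_blocks, wg$clahe_clip)
  red_e <- enhance_contrast(red, wg$clahe_blocks, wg$clahe_clip)
  gb <- function(img) from_ebimage(EBImage::gblur(as_ebimage(img),
                                                  sigma = wg$local_sigma))
  ratio_mask <- function(img) img / pmax(gb(img), 1e-3) < wg$ratio_threshold
  brush3 <- EBImage::makeBrush(3, "disc")
  body_dil <- from_ebimage(EBImage::dilate(as_ebimage(body_mask * 1),
                                           EBImage::makeBrush(7, "disc"))) > 0.5
  # membrane band gates the off-body search to the wing blades; an area
  # filter drops the thin luminance-ramp sleeves along leg and body edges
  mem <- blue > 0.62 & blue < 0.88 & !body_dil
  mem <- from_ebimage(EBImage::closing(as_ebimage(mem * 1),
                                       EBImage::makeBrush(5, "disc"))) > 0.5
  mlab <- from_ebimage(EBImage::bwlabel(as_ebimage(mem * 1)))
  msz <- tabulate(mlab[mlab > 0])
  mem <- mem & matrix(mlab %in% which(msz >= 400), nrow(mem))
  mem <- from_ebimage(EBImage::fillHull(as_ebimage(mem * 1))) > 0.5
  gate <- from_ebimage(EBImage::dilate(as_ebimage(mem * 1),
                                       EBImage::makeBrush(5, "disc"))) > 0.5
  struct_blue <- ratio_mask(blue_e) & !body_dil & gate
  # red channel: the local background is estimated separately on the bright
  # (transilluminated body) and dark (off-body) domains by normalized
  # convolution, so the body boundary produces no spurious contrast ring
  # and vein segments right at the boundary notches are kept
  # the body mask (thresholded blue silhouette) is already tighter than the
  # bright red body, so it can serve as the inside domain directly
  body_in <- body_mask
  red_ratio <- function(support_in, support_out) {
    loc_in <- gb(red_e * support_in) / pmax(gb(support_in * 1), 1e-3)
    loc_out <- gb(red_e * support_out) / pmax(gb(support_out * 1), 1e-3)
    loc <- ifelse(body_in, loc_in, loc_out)
    red_e / pmax(loc, 1e-3) < wg$ratio_threshold
  }
  # two passes: the second estimates the local background with first-pass
  # detections excluded, so the cores of thick structures (the vein
  # convergence at the hinge) cannot suppress their own contrast
  det1 <- red_ratio(body_in, !body_mask)
  struct_red <- red_ratio(body_in & !det1, !body_mask & !det1)
  # off the body, only accept red detections inside the wing blades
  # (keeps leg silhouettes out of the structure set)
  struct_red <- struct_red & (body_mask | gate)
  if (!is.null(roi_rows)) {
    keep <- rep(FALSE, nrow(red))
    keep[roi_rows] <- TRUE
    struct_red <- struct_red & keep
  }
  mask <- struct_blue | struct_red
  if (!any(mask)) stop("wing not found")
  # component cleanup with 1-px bridging across the body boundary
  bridged <- from_ebimage(EBImage::dilate(as_ebimage(mask * 1), brush3)) > 0.5
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(bridged * 1)))
  sizes <- tabulate(lab[mask])
  keep_ids <- which(sizes >= wg$min_object_px)
  if (length(keep_ids) == 0) stop("wing not found")
  mask & matrix(lab %in% keep_ids, nrow(mask))
}

#' Split a wing-structure mask into left and right wings
#'
#' Connected components (with 1-px bridging) are assigned to the left or
#' right of the body axis by their centroid.
#'
#' @param mask logical structure mask.
#' @param axis_x x (column) position of the body axis.
#' @return list with logical masks `left`, `right` (either may be empty).
#' @export
split_wing_sides <- function(mask, axis_x) {
  bridged <- from_ebimage(EBImage::dilate(as_ebimage(mask * 1),
                                          EBImage::makeBrush(3, "disc"))) > 0.5
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(bridged * 1)))
  lab[!mask] <- 0
  ids <- sort(unique(lab[lab > 0]))
  left <- matrix(FALSE, nrow(mask), ncol(mask))
  right <- left
  for (id in ids) {
    sel <- lab == id
    cx <- mean(col(mask)[sel])
    if (cx < axis_x) left <- left | sel else right <- right | sel
  }
  list(left = left, right = right)
}

#' Topological skeleton (Zhang-Suen thinning)
#'
#' Iterative thinning to a 1-px-wide, connectivity-preserving skeleton.
#' The skeleton is always a subset of the input mask.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize_wing <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) return(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  m <- pad
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    rs <- (1 + max(0, dr)):(nrow(x) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(x) + min(0, dc))
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nr + 1), 2:(nc + 1)]
}

# ---------------------------------------------------------------------------
# B-spline basis helpers (cubic), built on splines::splineDesign.

bspline_basis_open <- function(t, K) {
  stopifnot(K >= 4)
  interior <- if (K > 4) seq(0, 1, length.out = K - 2)[2:(K - 3)] else numeric(0)
  knots <- c(rep(0, 4), interior, rep(1, 4))
  splines::splineDesign(knots, clamp(t, 0, 1), ord = 4)
}

bspline_basis_periodic <- function(t, K) {
  stopifnot(K >= 4)
  h <- 1 / K
  knots <- seq(-3, K + 3) * h
  B <- splines::splineDesign(knots, t %% 1, ord = 4)
  Bp <- B[, 1:K, drop = FALSE]
  Bp[, 1:3] <- Bp[, 1:3] + B[, K + (1:3), drop = FALSE]
  Bp
}

# Least-squares B-spline fit. `anchor` (a K x 2 control-point matrix, e.g.
# from the transformed template) regularizes spans with little or no data
# towards the template shape instead of towards zero.
fit_bspline_curve <- function(t, pts, K, periodic = FALSE, ridge = 1e-6,
                              anchor = NULL, anchor_weight = 0.25) {
  B <- if (periodic) bspline_basis_periodic(t, K) else bspline_basis_open(t, K)
  if (is.null(anchor)) {
    A <- crossprod(B) + diag(ridge, ncol(B))
    ctrl <- solve(A, crossprod(B, pts))
  } else {
    A <- crossprod(B) + diag(anchor_weight, ncol(B))
    ctrl <- solve(A, crossprod(B, pts) + anchor_weight * anchor)
  }
  list(ctrl = ctrl, K = K, periodic = periodic)
}

# Control points reproducing a densely sampled curve (for template anchors).
curve_to_ctrl <- function(t, pts, K, periodic = FALSE) {
  B <- if (periodic) bspline_basis_periodic(t, K) else bspline_basis_open(t, K)
  qr.solve(crossprod(B) + diag(1e-8, ncol(B)), crossprod(B, pts))
}

eval_bspline_curve <- function(fit, t) {
  B <- if (fit$periodic) bspline_basis_periodic(t, fit$K)
       else bspline_basis_open(t, fit$K)
  B %*% fit$ctrl
}

# ---------------------------------------------------------------------------

#' Wing template
#'
#' The canonical wing used both as the fitting template and as the mean
#' shape of the generator: outline plus veins L2-L5 with the hinge at the
#' origin and unit wing length. Densely sampled curves carry their curve
#' parameters for the point-assignment step of the fit.
#'
#' @param aspect outline aspect ratio.
#' @return list with `points` (n x 2), `curve` (labels), `t` (parameters),
#'   `hinge`, `anchors`.
#' @export
wing_template <- function(aspect = 0.235) {
  canon <- canonical_wing(aspect = aspect)
  samp <- sample_canonical_wing(canon, n_outline = 200, n_vein = 40)
  pts <- samp$outline$pts
  curve <- rep("outline", nrow(pts))
  tpar <- samp$outline$t
  for (k in names(samp$veins)) {
    pts <- rbind(pts, samp$veins[[k]]$pts)
    curve <- c(curve, rep(k, nrow(samp$veins[[k]]$pts)))
    tpar <- c(tpar, samp$veins[[k]]$t)
  }
  list(points = pts, curve = curve, t = tpar,
       hinge = canon$hinge, anchors = canon$anchors)
}

# Closed-form similarity (scale, proper rotation, translation) minimizing
# |P - (s R Q + t)|^2 over matched rows of P (targets) and Q (sources).
fit_similarity <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  H <- crossprod(Q0, P0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(diag(D) * sv$d) / sum(Q0^2)
  t_vec <- cP - s * as.vector(R %*% cQ)
  list(s = s, R = R, t = t_vec)
}

apply_similarity <- function(tr, Q) {
  sweep(Q %*% t(tr$R) * tr$s, 2, -tr$t)
}

#' Fit the wing template to a skeleton
#'
#' Initializes a similarity transform (scale, rotation, translation, and
#' chirality chosen over four candidates) from the principal axis of the
#' skeleton point set, refines it by trimmed iterative closest point
#' matching against the densely sampled template, then assigns skeleton
#' points to their nearest template curve and refits each curve as a cubic
#' B-spline (periodic with 12 control points for the outline, clamped with
#' 6 per vein) by least squares, iterating assignment and refit until the
#' control points move less than `tol_px` or `max_iter` is reached.
#' Landmarks: each vein's distal end is projected onto the fitted outline;
#' the hinge is the convergence point of the fitted veins' proximal ends
#' (template anchor as fallback).
#'
#' @param skeleton logical skeleton matrix, or an n x 2 (x, y) point matrix.
#' @param template a [wing_template()].
#' @param config an [fw_config()].
#' @param side `"left"`, `"right"` or `NA` (recorded in the model).
#' @return object of class `wing_model`: fitted `outline` and `veins`
#'   B-splines, `hinge`, `landmarks`, `wl_px`, `ww_px`, `wa_px2`,
#'   `converged`, `fit_quality` (mean skeleton-to-curve distance, px),
#'   `veins_fitted` (named logical).
#' @export
fit_wing_splines <- function(skeleton, template = wing_template(),
                             config = fw_config(), side = NA) {
  wg <- config$wing
  P <- if (is.matrix(skeleton) && !is.logical(skeleton)) {
    skeleton
  } else {
    idx <- which(skeleton, arr.ind = TRUE)
    cbind(x = idx[, 2], y = idx[, 1])
  }
  if (nrow(P) < 40) stop("skeleton too small for wing fitting")
  Q_all <- template$points

  # --- initialization over 4 candidates (2 axis directions x 2 chiralities)
  pP <- stats::prcomp(P)
  vP <- pP$rotation[, 1]
  eP <- diff(range(P %*% vP))
  best <- NULL
  for (chir in c(1, -1)) {
    Qc <- Q_all %*% diag(c(1, chir))
    pQ <- stats::prcomp(Qc)
    vQ <- pQ$rotation[, 1]
    eQ <- diff(range(Qc %*% vQ))
    for (flip in c(1, -1)) {
      v2 <- flip * vP
      ang <- atan2(v2[2], v2[1]) - atan2(vQ[2], vQ[1])
      R0 <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      s0 <- eP / eQ
      t0 <- colMeans(P) - s0 * as.vector(R0 %*% colMeans(Qc))
      tr <- list(s = s0, R = R0, t = t0)
      Tq <- apply_similarity(tr, Qc)
      d <- sqrt(rowSums((P - Tq[nearest_index(P, Tq), ])^2))
      score <- mean(d)
      if (is.null(best) || score < best$score) {
        best <- list(tr = tr, chir = chir, score = score)
      }
    }
  }
  chir <- best$chir
  Qc <- Q_all %*% diag(c(1, chir))
  tr <- best$tr

  # --- trimmed ICP on the similarity transform
  for (it in 1:12) {
    Tq <- apply_similarity(tr, Qc)
    ni <- nearest_index(P, Tq)
    d <- sqrt(rowSums((P - Tq[ni, ])^2))
    keep <- d <= stats::quantile(d, 0.92)
    tr_new <- fit_similarity(P[keep, , drop = FALSE],
                             Qc[ni[keep], , drop = FALSE])
    delta <- max(abs(tr_new$t - tr$t)) + abs(tr_new$s - tr$s) * 100
    tr <- tr_new
    if (delta < 0.05) break
  }

  # --- curve assignment + B-spline refit loop
  curves <- c("outline", "L2", "L3", "L4", "L5")
  Kmap <- c(outline = 12, L2 = 6, L3 = 6, L4 = 6, L5 = 6)
  Tq <- apply_similarity(tr, Qc)
  # template anchors: control points reproducing each transformed template
  # curve; they stabilize spline spans with sparse skeleton support
  anchors <- list()
  for (cv in curves) {
    sel <- template$curve == cv
    anchors[[cv]] <- curve_to_ctrl(template$t[sel], Tq[sel, , drop = FALSE],
                                   K = Kmap[[cv]], periodic = cv == "outline")
  }
  ni <- nearest_index(P, Tq)
  pt_curve <- template$curve[ni]
  pt_t <- template$t[ni]
  fits <- list()
  converged <- FALSE
  prev_ctrl <- NULL
  for (it in seq_len(wg$max_iter)) {
    fits <- list()
    for (cv in curves) {
      sel <- pt_curve == cv
      if (sum(sel) < 12 || diff(range(pt_t[sel])) < 0.3) {
        fits[[cv]] <- NULL
        next
      }
      fits[[cv]] <- fit_bspline_curve(pt_t[sel], P[sel, , drop = FALSE],
                                      K = Kmap[[cv]],
                                      periodic = cv == "outline",
                                      anchor = anchors[[cv]])
    }
    if (is.null(fits$outline)) stop("wing outline could not be fitted")
    # dense samples of the fitted curves for reassignment
    ref_pts <- NULL; ref_curve <- NULL; ref_t <- NULL
    for (cv in names(fits)) {
      ts <- if (cv == "outline") seq(0, 1 - 1 / 400, length.out = 400)
            else seq(0, 1, length.out = 120)
      pts <- eval_bspline_curve(fits[[cv]], ts)
      ref_pts <- rbind(ref_pts, pts)
      ref_curve <- c(ref_curve, rep(cv, length(ts)))
      ref_t <- c(ref_t, ts)
    }
    ni <- nearest_index(P, ref_pts)
    d_assign <- sqrt(rowSums((P - ref_pts[ni, , drop = FALSE])^2))
    # contamination guard: points far from every fitted curve (stray leg
    # or bristle fragments) take no part in the next refit
    pt_curve <- ref_curve[ni]
    pt_t <- ref_t[ni]
    pt_curve[d_assign > 5] <- "drop"
    ctrl_now <- do.call(rbind, lapply(fits, `[[`, "ctrl"))
    if (!is.null(prev_ctrl) && identical(dim(prev_ctrl), dim(ctrl_now))) {
      if (max(abs(prev_ctrl - ctrl_now)) < wg$tol_px) {
        converged <- TRUE
        break
      }
    }
    prev_ctrl <- ctrl_now
  }

  veins_fitted <- vapply(c("L2", "L3", "L4", "L5"),
                         function(k) !is.null(fits[[k]]), logical(1))

  # --- landmarks
  out_dense <- eval_bspline_curve(fits$outline,
                                  seq(0, 1 - 1 / 2048, length.out = 2048))
  landmarks <- list()
  for (k in c("L2", "L3", "L5")) {
    if (!veins_fitted[[k]]) next
    tip <- eval_bspline_curve(fits[[k]], 1)
    i <- nearest_index(tip, out_dense)
    landmarks[[k]] <- out_dense[i, ]
  }
  prox <- do.call(rbind, lapply(names(which(veins_fitted)), function(k)
    eval_bspline_curve(fits[[k]], 0)))
  hinge_tpl <- as.vector(tr$s * tr$R %*% (template$hinge * c(1, chir))) + tr$t
  hinge <- if (!is.null(prox) && nrow(prox) >= 2 &&
               max(stats::dist(prox)) <= 8) colMeans(prox) else hinge_tpl

  wl <- if (!is.null(landmarks$L3)) sqrt(sum((hinge - landmarks$L3)^2)) else NA_real_
  ww <- if (!is.null(landmarks$L2) && !is.null(landmarks$L5)) {
    sqrt(sum((landmarks$L2 - landmarks$L5)^2))
  } else NA_real_
  out512 <- eval_bspline_curve(fits$outline,
                               seq(0, 1 - 1 / 512, length.out = 512))
  wa <- shoelace_area(out512)

  dq <- sqrt(rowSums((P - ref_pts[nearest_index(P, ref_pts), ])^2))
  structure(list(outline = fits$outline,
                 veins = fits[intersect(names(fits), c("L2", "L3", "L4", "L5"))],
                 veins_fitted = veins_fitted,
                 hinge = hinge, landmarks = landmarks,
                 transform = tr, chirality = chir,
                 wl_px = wl, ww_px = ww, wa_px2 = wa,
                 converged = converged, fit_quality = mean(dq),
                 side = side),
            class = "wing_model")
}

#' @export
print.wing_model <- function(x, ...) {
  cat(sprintf(
    "<wing_model> side=%s  WL=%.1f  WW=%.1f  WA=%.0f px  (fit %.2f px, %s)\n",
    x$side, x$wl_px, x$ww_px, x$wa_px2, x$fit_quality,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Wing measurements in px and mm
#'
#' Wing length is the distance from the hinge to the outline-L3
#' intersection; wing width the distance between the outline-L2 and
#' outline-L5 intersections; wing area the shoelace area of the fitted
#' outline sampled at 512 points. Missing landmarks yield `NA`, never 0.
#'
#' @param model a `wing_model`.
#' @param mm_per_px pixel calibration.
#' @return list `(wl_px, ww_px, wa_px2, wl_mm, ww_mm, wa_mm2, side,
#'   converged)`.
#' @export
wing_measurements <- function(model, mm_per_px = NA) {
  list(wl_px = model$wl_px, ww_px = model$ww_px, wa_px2 = model$wa_px2,
       wl_mm = model$wl_px * mm_per_px, ww_mm = model$ww_px * mm_per_px,
       wa_mm2 = model$wa_px2 * mm_per_px^2,
       side = model$side, converged = model$converged)
}

#' Measure the wings of an aligned sequence
#'
#' Runs structure extraction on the brightest red frame (and its blue
#' counterpart), splits the structures by body side, skeletonizes and fits
#' each side, and returns the side with the better fit quality.
#'
#' @param stack an `aligned_stack` with red frames.
#' @param body_model a `body_model`.
#' @param config an [fw_config()].
#' @return a `wing_model`, or `NULL` (with a warning) when no wing fits.
#' @export
measure_wings <- function(stack, body_model, config = fw_config()) {
  bright <- select_brightest_red_frame(stack, body_model)
  blue <- stack$frames[[bright]]
  red <- stack$red_frames[[bright]]
  body_mask <- body_model$labels > 0
  thorax_rows <- which(rowSums(body_model$labels == 2) > 0)
  roi_rows <- min(thorax_rows):nrow(red)
  mask <- wing_mask_two_channel(blue, red, body_mask, config,
                                roi_rows = roi_rows)
  sides <- split_wing_sides(mask, axis_x = body_model$thorax$center[1])
  models <- list()
  for (sd in c("left", "right")) {
    if (sum(sides[[sd]]) < 100) next
    skel <- skeletonize_wing(sides[[sd]])
    models[[sd]] <- tryCatch(
      fit_wing_splines(skel, config = config, side = sd),
      error = function(e) NULL)
  }
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) {
    warning("no wing could be fitted")
    return(NULL)
  }
  qual <- vapply(models, `[[`, numeric(1), "fit_quality")
  models[[which.min(qual)]]
}
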