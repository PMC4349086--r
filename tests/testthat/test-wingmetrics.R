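# Wing-structure extraction, skeletonization and B-spline template fitting.

test_that("CLAHE is bounded and leaves constants alone", {
  const <- matrix(0.5, 64, 64)
  expect_equal(enhance_contrast(const), const)
  set.seed(3)
  img <- matrix(0.5, 64, 64)
  img[30:34, ] <- 0.48                     # faint band
  img <- img + matrix(stats::rnorm(64 * 64, 0, 0.002), 64)
  out <- enhance_contrast(img)
  expect_true(all(out >= 0 & out <= 1))
  # local contrast across the faint structure increases
  grad_pre <- mean(abs(img[29, ] - img[31, ]))
  grad_post <- mean(abs(out[29, ] - out[31, ]))
  expect_gt(grad_post, grad_pre)
})

test_that("skeletonization thins to 1 px and preserves topology", {
  bar <- matrix(FALSE, 30, 60)
  bar[13:17, 10:50] <- TRUE
  sk <- skeletonize_wing(bar)
  expect_true(all(sk[!bar] == FALSE))          # skeleton inside the mask
  expect_true(all(colSums(sk[, 14:46]) == 1))  # 1 px wide along the bar
  expect_gte(sum(sk), 36)                      # length within ~10% of bar
  expect_lt(sum(sk), 43)
  # annulus -> a single closed 1 px loop (every pixel has 2+ neighbours)
  ann <- ellipse_mask(60, 60, c(30, 30), 20, 20) &
    !ellipse_mask(60, 60, c(30, 30), 14, 14)
  ska <- skeletonize_wing(ann)
  idx <- which(ska, arr.ind = TRUE)
  nbrs <- vapply(seq_len(nrow(idx)), function(i) {
    sum(ska[max(1, idx[i, 1] - 1):min(60, idx[i, 1] + 1),
            max(1, idx[i, 2] - 1):min(60, idx[i, 2] + 1)]) - 1
  }, numeric(1))
  expect_true(all(nbrs >= 2))
})

test_that("wing structures are recovered by the two-channel mask", {
  fx <- fw_fixture("female")
  bright <- select_brightest_red_frame(fx$stack, fx$bm)
  wmask <- wing_mask_two_channel(
    fx$stack$frames[[bright]], fx$stack$red_frames[[bright]],
    fx$bm$labels > 0,
    roi_rows = min(which(rowSums(fx$bm$labels == 2) > 0)):nrow(fx$proj))
  # ground truth: the generating outline+vein strokes mapped to the
  # aligned frame
  w <- fx$truth$wings$right
  curves <- c(list(rbind(w$outline, w$outline[1, ])), w$veins)
  mapped <- lapply(curves, function(pts)
    t(apply(pts, 1, function(p) map_body_point(fx, p, frame = bright))))
  truth_mask <- rasterize_strokes(mapped, nrow(wmask), ncol(wmask))
  # tolerant overlap (1 px dilation both ways): the warp blurs edges
  dil <- function(m) flywalk:::from_ebimage(EBImage::dilate(
    flywalk:::as_ebimage(m * 1), EBImage::makeBrush(3, "disc"))) > 0.5
  right_half <- col(wmask) > fx$bm$thorax$center[1]
  got <- wmask & right_half
  want <- truth_mask & right_half
  expect_gt(sum(got & dil(want)) / sum(got), 0.9)   # precision
  expect_gt(sum(want & dil(got)) / sum(want), 0.9)  # recall
  # the body-overlap region is recovered from the red channel
  inbody <- want & (fx$bm$labels > 0)
  expect_gt(sum(inbody & dil(got)) / sum(inbody), 0.8)
})

test_that("template fitting recovers a known wing to about a percent", {
  for (sd in c(3, 11, 29)) {
    truth <- sample_fly(sd, sex = "female")
    w <- truth$wings$right
    allpts <- rbind(w$outline, do.call(rbind, w$veins))
    off <- c(-min(allpts[, 1]) + 10, -min(allpts[, 2]) + 10)
    shift <- function(p) sweep(p, 2, -off)
    curves <- c(list(rbind(w$outline, w$outline[1, ])), w$veins)
    nr <- ceiling(diff(range(allpts[, 2]))) + 20
    nc <- ceiling(diff(range(allpts[, 1]))) + 20
    m <- rasterize_strokes(lapply(curves, shift), nr, nc)
    wm <- fit_wing_splines(skeletonize_wing(m), side = "right")
    expect_true(all(wm$veins_fitted))
    expect_equal(wm$wl_px, truth$wl_px, tolerance = 0.02)
    expect_equal(wm$ww_px, truth$ww_px, tolerance = 0.02)
    expect_equal(wm$wa_px2, truth$wa_px2, tolerance = 0.02)
    expect_lt(wm$fit_quality, 0.6)
  }
})

test_that("measurements obey the similarity scaling law", {
  truth <- sample_fly(17, sex = "female")
  w <- truth$wings$right
  allpts <- rbind(w$outline, do.call(rbind, w$veins))
  off <- c(-min(allpts[, 1]) + 10, -min(allpts[, 2]) + 10)
  curves <- c(list(rbind(w$outline, w$outline[1, ])), w$veins)
  nr <- ceiling(diff(range(allpts[, 2]))) + 20
  nc <- ceiling(diff(range(allpts[, 1]))) + 20
  m <- rasterize_strokes(lapply(curves, function(p) sweep(p, 2, -off)), nr, nc)
  sk <- skeletonize_wing(m)
  base <- fit_wing_splines(sk, side = "right")
  pts <- which(sk, arr.ind = TRUE)
  scaled <- fit_wing_splines(cbind(x = pts[, 2] * 1.3, y = pts[, 1] * 1.3),
                             side = "right")
  expect_equal(scaled$wl_px / base$wl_px, 1.3, tolerance = 0.01)
  expect_equal(scaled$ww_px / base$ww_px, 1.3, tolerance = 0.01)
  expect_equal(scaled$wa_px2 / base$wa_px2, 1.69, tolerance = 0.01)
})

test_that("a missing vein is flagged but WL and WW survive", {
  truth <- sample_fly(23, sex = "female")
  w <- truth$wings$right
  allpts <- rbind(w$outline, do.call(rbind, w$veins))
  off <- c(-min(allpts[, 1]) + 10, -min(allpts[, 2]) + 10)
  curves <- c(list(rbind(w$outline, w$outline[1, ])),
              w$veins[c("L2", "L3", "L5")])      # L4 erased
  nr <- ceiling(diff(range(allpts[, 2]))) + 20
  nc <- ceiling(diff(range(allpts[, 1]))) + 20
  m <- rasterize_strokes(lapply(curves, function(p) sweep(p, 2, -off)), nr, nc)
  wm <- fit_wing_splines(skeletonize_wing(m), side = "right")
  expect_false(wm$veins_fitted[["L4"]])
  expect_true(is.finite(wm$wl_px))
  expect_true(is.finite(wm$ww_px))
  expect_equal(wm$wl_px, truth$wl_px, tolerance = 0.03)
})

test_that("enclosed area follows the shoelace definition", {
  # circle of radius 50 sampled at 512 points: area pi r^2 to 0.1%
  t <- seq(0, 2 * pi, length.out = 513)[-513]
  circle <- cbind(100 + 50 * cos(t), 100 + 50 * sin(t))
  expect_equal(flywalk:::shoelace_area(circle), pi * 50^2,
               tolerance = 0.001)
  # Monte-Carlo point-in-polygon oracle on a random smooth outline
  set.seed(9)
  r <- 40 + 6 * sin(3 * t) + 3 * cos(5 * t)
  poly <- cbind(80 + r * cos(t), 80 + r * sin(t))
  xs <- stats::runif(40000, 0, 160); ys <- stats::runif(40000, 0, 160)
  inside <- flywalk:::point_in_polygon(xs, ys, poly)
  mc <- mean(inside) * 160^2
  expect_equal(flywalk:::shoelace_area(poly), mc, tolerance = 0.02)
})

test_that("full-pipeline wing measurement stays close to ground truth", {
  for (nm in c("female", "male")) {
    fx <- fw_fixture(nm)
    wm <- measure_wings(fx$stack, fx$bm)
    expect_false(is.null(wm))
    expect_equal(wm$wl_px, fx$truth$wl_px, tolerance = 0.05)
    expect_equal(wm$ww_px, fx$truth$ww_px, tolerance = 0.05)
    expect_equal(wm$wa_px2, fx$truth$wa_px2, tolerance = 0.05)
    meas <- wing_measurements(wm, mm_per_px = 0.02)
    expect_equal(meas$wl_mm, wm$wl_px * 0.02)
    expect_equal(meas$wa_mm2, wm$wa_px2 * 0.02^2)
  }
})
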