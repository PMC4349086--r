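# Alignment, temporal percentile projection, threshold/cleanup, watershed.

test_that("subtraction and complement follow the dark-fly convention", {
  bg <- matrix(0.9, 20, 20)
  expect_equal(subtract_and_complement(bg, bg), matrix(1, 20, 20))
  frame <- bg; frame[8:12, 8:12] <- 0.2       # dark fly in blue
  comp <- subtract_and_complement(frame, bg)
  expect_lt(comp[10, 10], comp[1, 1])         # fly dark on bright field
  expect_equal(comp[1, 1], 1)
  expect_equal(1 - comp[10, 10], 0.7)         # involution recovers the diff
  expect_error(subtract_and_complement(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape mismatch")
})

test_that("moment alignment recovers known translations and rotations", {
  # asymmetric two-blob 'fly': big blob (abdomen) below small blob (head)
  base <- function(center, theta) {
    m <- matrix(1, 161, 161)
    m[ellipse_mask(161, 161, center, a = 40, b = 18, theta = theta)] <- 0.2
    hx <- center[1] - 58 * sin(theta); hy <- center[2] - 58 * cos(theta)
    m[ellipse_mask(161, 161, c(hx, hy), a = 16, b = 14, theta = theta)] <- 0.2
    m
  }
  ref <- base(c(81, 85), 0)
  st0 <- moments_align(list(ref))
  expect_lt(abs(st0$transforms[[1]]$theta) * 180 / pi, 0.5)
  # known translation
  sh <- base(c(81 + 10, 85 - 7), 0)
  st <- moments_align(list(sh))
  expect_equal(st$transforms[[1]]$centroid[1] - st0$transforms[[1]]$centroid[1],
               10, tolerance = 0.5)
  expect_equal(st$transforms[[1]]$centroid[2] - st0$transforms[[1]]$centroid[2],
               -7, tolerance = 0.5)
  # known rotation: rotate the reference image itself and recover the angle
  rot <- flywalk:::warp_rigid(ref, theta = 20 * pi / 180,
                              in_center = c(81, 85), out_center = c(81, 85),
                              fill = 1)
  str <- moments_align(list(rot))
  expect_equal(abs(str$transforms[[1]]$theta) * 180 / pi, 20, tolerance = 0.5)
  # flip convention: the wide end goes below the centre
  upside <- ref[161:1, 161:1]
  stf <- moments_align(list(upside))
  al <- stf$frames[[1]]
  wid <- rowSums(1 - al > 0.45)
  expect_gt(which.max(wid), 81)
  expect_warning(moments_align(list(matrix(1, 20, 20), ref)), "zero-mass")
})

test_that("percentile projection equals the order-statistic definition", {
  # identical frames project to themselves
  f <- matrix(stats::runif(64), 8, 8)
  expect_equal(percentile_projection(list(f, f, f)), f)
  # pixel dark in 1 of 40 frames, bright in 39 -> bright at q = 95
  frames <- c(replicate(39, matrix(200 / 255, 4, 4), simplify = FALSE),
              list(matrix(10 / 255, 4, 4)))
  expect_equal(percentile_projection(frames, 95)[1, 1], 200 / 255)
  # q = 0 is the per-pixel minimum
  expect_equal(percentile_projection(frames, 0)[2, 2], 10 / 255)
  expect_error(percentile_projection(frames, 101), "outside")
  # brute-force oracle: per-pixel stats::quantile type 7 on random stacks
  for (seed in 1:3) {
    set.seed(seed)
    stack <- replicate(5, matrix(stats::runif(64), 8, 8), simplify = FALSE)
    for (q in c(37, 80, 95)) {
      got <- percentile_projection(stack, q)
      arr <- simplify2array(stack)
      want <- apply(arr, c(1, 2), stats::quantile, probs = q / 100,
                    type = 7, names = FALSE)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("moving thin legs vanish under the 95th-percentile projection", {
  # static body, 2 px leg at a different place in each of 20 frames
  frames <- lapply(1:20, function(k) {
    m <- matrix(1, 80, 80)
    m[ellipse_mask(80, 80, c(40, 40), a = 25, b = 12)] <- 0.2
    leg_col <- 5 + (k * 3) %% 70
    m[20:60, leg_col + 0:1] <- 0.3
    m
  })
  proj <- percentile_projection(frames, 95)
  body <- ellipse_mask(80, 80, c(40, 40), a = 26, b = 13)
  expect_true(all(proj[!body] > 0.9))
})

test_that("binarization removes bristles and degenerate inputs error", {
  img <- matrix(1, 100, 100)
  img[ellipse_mask(100, 100, c(50, 50), a = 30, b = 15)] <- 0.2
  img[50, 66:85] <- 0.2                       # 1 px 'bristle'
  img[30, 66:75] <- 0.55                      # fainter vein-like structure
  mask <- binarize_and_close(img)
  expect_false(any(mask[50, 70:85]))          # bristle gone
  expect_false(any(mask[30, 66:75]))          # vein never enters
  expect_true(mask[50, 50])
  expect_error(binarize_and_close(img, threshold = 0.05), "no fly")
})

test_that("watershed recovers the three generating lobes", {
  mask <- ellipse_mask(200, 90, c(45, 40), a = 17, b = 20) |
    ellipse_mask(200, 90, c(45, 82), a = 30, b = 22) |
    ellipse_mask(200, 90, c(45, 140), a = 46, b = 27)
  segs <- watershed_segments(mask)
  expect_equal(sort(unique(as.vector(segs$labels[segs$labels > 0]))), 1:3)
  bm <- fit_segment_templates(segs)
  expect_lt(abs(bm$head$center[2] - 40), 3)
  expect_lt(abs(bm$thorax$center[2] - 82), 3)
  expect_lt(abs(bm$abdomen$center[2] - 140), 3)
  # labels partition the mask
  expect_equal(sum(segs$labels > 0), sum(mask))
  # degenerate: a single circle has no three necks
  circle <- ellipse_mask(80, 80, c(40, 40), a = 20, b = 20)
  expect_error(watershed_segments(circle), "segmentation failed")
})

test_that("segment areas are ordered head < thorax < abdomen on renders", {
  fx <- fw_fixture("female")
  areas <- tabulate(fx$segs$labels[fx$segs$labels > 0], nbins = 3)
  expect_true(areas[1] < areas[2] && areas[2] < areas[3])
  # head segment sits at the top of the aligned frame
  head_rows <- which(rowSums(fx$segs$labels == 1) > 0)
  abd_rows <- which(rowSums(fx$segs$labels == 3) > 0)
  expect_lt(max(head_rows), min(abd_rows))
})

test_that("moment ellipse fits are exact on exact ellipses", {
  labs <- matrix(0L, 260, 140)
  labs[ellipse_mask(260, 140, c(70, 40), a = 22, b = 20)] <- 1L
  labs[ellipse_mask(260, 140, c(70, 120), a = 50, b = 20)] <- 2L
  labs[ellipse_mask(260, 140, c(70, 215), a = 35, b = 35)] <- 3L
  bm <- fit_segment_templates(structure(list(labels = labs, markers = NULL),
                                        class = "body_segments"))
  expect_equal(bm$thorax$semi_major, 50, tolerance = 1)
  expect_equal(bm$thorax$semi_minor, 20, tolerance = 1)
  expect_equal(bm$abdomen$semi_major, bm$abdomen$semi_minor, tolerance = 1)
})

test_that("shoulder width scales with the thorax template", {
  fit <- list(width = 40)
  expect_equal(shoulder_width(fit, list(reference_width = 40,
                                        shoulder_width = 40)), 40)
  fit$width <- 50
  expect_equal(shoulder_width(fit, list(reference_width = 40,
                                        shoulder_width = 40)), 50)
})
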