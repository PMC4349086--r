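# Brightest-frame selection, ocelli template matching, eye edges and IOD.

test_that("brightest red frame matches the brute-force argmax", {
  frames <- list(matrix(0.3, 10, 10), matrix(0.45, 10, 10),
                 matrix(0.4, 10, 10))
  expect_equal(select_brightest_red_frame(frames), 2)
  # tie goes to the first frame
  expect_equal(select_brightest_red_frame(list(matrix(0.3, 5, 5),
                                               matrix(0.3, 5, 5))), 1)
  fx <- fw_fixture("female")
  means <- vapply(fx$stack$red_frames, function(fr)
    mean(fr[fx$bm$labels > 0]), numeric(1))
  expect_equal(select_brightest_red_frame(fx$stack, fx$bm), which.max(means))
})

test_that("head ROI contains the ocelli and errors without a head", {
  fx <- fw_fixture("female")
  bright <- select_brightest_red_frame(fx$stack, fx$bm)
  red <- fx$stack$red_frames[[bright]]
  roi <- locate_head(red, fx$bm)
  dots <- which(red > 0.9, arr.ind = TRUE)
  expect_gt(nrow(dots), 0)
  expect_true(all(dots[, 1] %in% roi$rows))
  expect_true(all(dots[, 2] %in% roi$cols))
  expect_error(locate_head(red, list(labels = NULL)), "no head segment")
})

test_that("ocelli template matching is sub-pixel accurate", {
  tpl <- ocelli_template()
  roi <- matrix(0.6, 80, 70)
  # insert the template pattern at a known sub-position (integer here)
  r0 <- 31; c0 <- 26                      # top-left of template block
  sz <- nrow(tpl$image)
  roi[r0:(r0 + sz - 1), c0:(c0 + sz - 1)] <-
    roi[r0:(r0 + sz - 1), c0:(c0 + sz - 1)] + 0.3 * tpl$image
  res <- match_ocelli(roi, tpl)
  want <- cbind(tpl$posterior[, 1] + c0 - 1, tpl$posterior[, 2] + r0 - 1)
  expect_lt(max(abs(res$posterior - want)), 0.5)
  # featureless ROI: no ocelli
  expect_error(match_ocelli(matrix(0.5, 60, 60) +
                              matrix(stats::rnorm(3600, 0, 0.01), 60), tpl),
               "ocelli not found")
})

test_that("ocelli separation is invariant to small rotations", {
  tpl <- ocelli_template()
  mk_roi <- function(theta) {
    n <- 81; c0 <- 41
    X <- rep(seq_len(n), each = n) - c0
    Y <- rep(seq_len(n), times = n) - c0
    xr <- cos(theta) * X - sin(theta) * Y
    yr <- sin(theta) * X + cos(theta) * Y
    dots <- rbind(c(-5.5, 2), c(5.5, 2), c(0, -4))
    v <- 0.6
    for (i in 1:3) {
      v <- v + 0.3 * exp(-((xr - dots[i, 1])^2 + (yr - dots[i, 2])^2) /
                           (2 * 1.4^2))
    }
    matrix(v, n, n)
  }
  sep0 <- {
    p <- match_ocelli(mk_roi(0), tpl)$posterior
    sqrt(sum((p[1, ] - p[2, ])^2))
  }
  sep5 <- {
    p <- match_ocelli(mk_roi(5 * pi / 180), tpl)$posterior
    sqrt(sum((p[1, ] - p[2, ])^2))
  }
  expect_equal(sep0, 11, tolerance = 0.05)
  expect_equal(sep5 / sep0, 1, tolerance = 0.01)
})

test_that("eye edges sit at luminance steps and give the IOD", {
  # synthetic head: bright cuticle band of half-width 60 px, dark eyes
  mk_frame <- function(blur_sigma = 0) {
    n <- 201
    X <- matrix(rep(seq_len(n), each = n) - 101, n)
    v <- ifelse(abs(X) > 60, 0.2, 0.8)
    m <- matrix(v, n, n)
    if (blur_sigma > 0) {
      m <- flywalk:::from_ebimage(EBImage::gblur(flywalk:::as_ebimage(m),
                                                 sigma = blur_sigma))
    }
    m
  }
  pair <- rbind(c(95, 101), c(107, 101))   # horizontal posterior pair
  hm <- eye_edges_and_iod(mk_frame(), pair, half_length = 90)
  expect_equal(hm$iod_px, 120, tolerance = 1)
  # symmetric blur hardly moves the edge centres
  hm2 <- eye_edges_and_iod(mk_frame(2), pair, half_length = 90)
  expect_lt(abs(hm2$iod_px - hm$iod_px), 1)
  # featureless profile: no edges
  expect_error(eye_edges_and_iod(matrix(0.5, 201, 201), pair,
                                 half_length = 90), "edges not found")
})

test_that("pipeline IOD matches the generated ground truth closely", {
  for (nm in c("female", "male")) {
    fx <- fw_fixture(nm)
    hm <- measure_head(fx$stack, fx$bm)
    expect_equal(hm$iod_px, fx$truth$iod_px, tolerance = 0.02)
  }
})
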