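# Frame-validity checks and the sequence decision.

test_that("clean renders pass every frame check", {
  fx <- fw_fixture("female")
  expect_true(all(vapply(fx$qc, `[[`, logical(1), "valid")))
  expect_true(fx$dec$accepted)
  expect_equal(fx$dec$n_valid, length(fx$seq$frames))
})

test_that("injected nuisances fail their matching check", {
  truth <- sample_fly(21, sex = "female")
  cfg <- render_config(n_frames = 5, seed = 77,
                       defocus_frames = 2, border_touch_frames = 3,
                       reflection_frames = 4, folded_wing_frames = 5)
  seq <- render_sequence(truth, cfg)
  qc <- qc_sequence(seq)
  expect_true(qc[[1]]$valid)
  expect_false(qc[[2]]$focus_ok)
  expect_false(qc[[3]]$border_ok)
  expect_false(qc[[4]]$reflection_ok)
  expect_false(qc[[5]]$symmetry_ok)
  for (k in 2:5) expect_false(qc[[k]]$valid)
})

test_that("focus metric behaves as a Laplacian-variance criterion", {
  expect_equal(check_focus(matrix(0.5, 50, 50), threshold = 1e-4),
               list(ok = FALSE, metric = 0))
  fx <- fw_fixture("female")
  frame <- fx$seq$frames[[1]]$blue
  diffm <- fx$seq$background$blue - frame
  fg <- diffm > 0.08
  sharp <- check_focus(frame, fw_config()$qc$focus_threshold, mask = fg)
  expect_true(sharp$ok)
  blurred_img <- flywalk:::from_ebimage(
    EBImage::gblur(flywalk:::as_ebimage(frame), sigma = 4))
  blurred <- check_focus(blurred_img, fw_config()$qc$focus_threshold,
                         mask = fg)
  expect_false(blurred$ok)
  expect_lt(blurred$metric, sharp$metric)
})

test_that("border clearance detects touching and empty masks", {
  m <- matrix(FALSE, 40, 40)
  m[15:25, 15:25] <- TRUE
  expect_true(check_border_clearance(m))
  m2 <- m; m2[1, 20] <- TRUE
  expect_false(check_border_clearance(m2))
  expect_false(check_border_clearance(matrix(FALSE, 40, 40)))
})

test_that("reflection check counts saturated wing pixels", {
  red <- matrix(0.1, 30, 30)
  region <- matrix(TRUE, 30, 30)
  expect_true(check_reflections(red, region)$ok)
  red[5:8, 5:8] <- 1
  res <- check_reflections(red, region)
  expect_false(res$ok)
  expect_equal(res$metric, 16 / 900)
})

test_that("orientation and alignment react to rotation and missing wings", {
  body <- ellipse_mask(120, 120, c(60, 60), a = 40, b = 15)
  wings <- ellipse_mask(120, 120, c(35, 75), a = 25, b = 12) |
    ellipse_mask(120, 120, c(85, 75), a = 25, b = 12)
  full <- body | wings
  ok <- check_orientation_and_alignment(full, body_core = body)
  expect_true(ok$orientation_ok)
  expect_true(ok$alignment_ok)
  rot <- ellipse_mask(120, 120, c(60, 60), a = 40, b = 15, theta = 25 * pi / 180)
  res <- check_orientation_and_alignment(rot)
  expect_false(res$alignment_ok)
  expect_gt(res$angle_deg, 20)
  body_only <- check_orientation_and_alignment(body, body_core = body)
  expect_false(body_only$orientation_ok)   # wing-area ratio ~ 0
})

test_that("symmetry is judged by mirror IoU about the body axis", {
  body <- ellipse_mask(120, 121, c(61, 60), a = 40, b = 15)
  res <- check_symmetry(body)
  expect_true(res$ok)
  expect_gte(res$iou, 0.99)
  # one 'wing' on a single side breaks symmetry
  asym <- body | ellipse_mask(120, 121, c(90, 75), a = 25, b = 14)
  expect_false(check_symmetry(asym, body_core = body)$ok)
  expect_false(check_symmetry(matrix(FALSE, 10, 10))$ok)
})

test_that("validate_frame rejects mismatched channel shapes", {
  fr <- list(blue = matrix(0.5, 10, 10), red = matrix(0.5, 10, 12))
  bg <- list(blue = matrix(0.5, 10, 10))
  expect_error(validate_frame(fr, bg), "shape mismatch")
})

test_that("sequences are accepted iff at least 3 frames are valid", {
  mk <- function(valid) lapply(valid, function(v) list(valid = v))
  expect_true(accept_sequence(mk(c(rep(TRUE, 3), rep(FALSE, 7))))$accepted)
  expect_false(accept_sequence(mk(c(rep(TRUE, 2), rep(FALSE, 8))))$accepted)
  expect_false(accept_sequence(list())$accepted)
  # monotonicity: adding a valid frame never flips accept -> reject
  set.seed(42)
  for (i in 1:50) {
    valid <- stats::runif(8) < 0.4
    before <- accept_sequence(mk(valid))$accepted
    after <- accept_sequence(mk(c(valid, TRUE)))$accepted
    expect_true(!before || after)
  }
})
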