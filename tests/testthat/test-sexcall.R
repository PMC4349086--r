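# Abdominal luminance profiles, template correlation, sex combs, fusion.

test_that("profiles are normalized and illumination-invariant", {
  seg <- ellipse_mask(100, 60, c(30, 50), a = 35, b = 20)
  red <- matrix(0.5, 100, 60)
  prof <- abdominal_profile(red, seg)
  expect_equal(mean(prof$values), 1, tolerance = 1e-6)
  expect_true(all(abs(prof$values - 1) < 1e-6))   # uniform -> flat
  expect_true(all(diff(prof$positions) > 0))
  # doubling the luminance leaves the normalized profile unchanged
  prof2 <- abdominal_profile(red * 0.4 / 0.5, seg)
  expect_equal(prof$values, prof2$values, tolerance = 1e-9)
  expect_error(abdominal_profile(red, matrix(FALSE, 100, 60)), "too small")
})

test_that("male profiles darken posteriorly and match the male template", {
  fx <- fw_fixture("male")
  bright <- select_brightest_red_frame(fx$stack, fx$bm)
  prof <- abdominal_profile(fx$stack$red_frames[[bright]],
                            fx$bm$labels == 3)
  expect_gt(mean(prof$values[1:25]), mean(prof$values[76:100]))
  tpl <- sex_templates()
  r <- correlate_templates(prof, tpl$male, tpl$female)
  expect_gt(r$r_male, r$r_female)
})

test_that("female profiles match the female template", {
  fx <- fw_fixture("female")
  bright <- select_brightest_red_frame(fx$stack, fx$bm)
  prof <- abdominal_profile(fx$stack$red_frames[[bright]],
                            fx$bm$labels == 3)
  tpl <- sex_templates()
  r <- correlate_templates(prof, tpl$male, tpl$female)
  expect_gt(r$r_female, r$r_male)
})

test_that("template correlation is zero-lag Pearson", {
  set.seed(1)
  v <- stats::runif(100)
  r <- correlate_templates(v, v, -v)
  expect_equal(r$r_male, 1)
  expect_equal(r$r_female, -1)
  # brute-force covariance-formula oracle
  a <- stats::rnorm(100); b <- stats::rnorm(100)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate_templates(a, b, b)$r_male, brute, tolerance = 1e-12)
  r0 <- suppressWarnings(correlate_templates(rep(1, 100), v, v))
  expect_equal(r0$r_male, 0)
  expect_warning(correlate_templates(rep(1, 100), v, v), "constant")
})

test_that("sex combs are detected in males and absent in females", {
  m <- fw_fixture("male")
  comb <- detect_sex_combs(m$stack$red_frames, m$bm)
  expect_true(comb$comb_detected)
  expect_gt(comb$comb_confidence, 0.3)
  f <- fw_fixture("female")
  combf <- detect_sex_combs(f$stack$red_frames, f$bm)
  expect_false(combf$comb_detected)
  expect_equal(combf$comb_confidence, 0)
})

test_that("elongated dark artifacts are rejected by eccentricity", {
  f <- fw_fixture("female")
  head_rows <- which(rowSums(f$bm$labels == 1) > 0)
  cx <- round(f$bm$head$center[1])
  r0 <- min(head_rows) - 20
  # paint an elongated dark bar (leg crossing the antennae)
  frames <- lapply(f$stack$red_frames, function(fr) {
    fr[r0 + 0:1, (cx - 18):(cx + 18)] <- 0.02
    fr
  })
  res <- detect_sex_combs(frames, f$bm)
  expect_false(res$comb_detected)
  # a compact dark blob at the same spot is accepted
  frames2 <- lapply(f$stack$red_frames, function(fr) {
    fr[(r0 - 1):(r0 + 2), (cx - 2):(cx + 1)] <- 0.02
    fr
  })
  res2 <- detect_sex_combs(frames2, f$bm)
  expect_true(res2$comb_detected)
})

test_that("evidence fusion follows the decision rule", {
  lum_f <- list(r_male = 0.2, r_female = 0.6)
  # strong comb evidence dominates a weak female luminance signal
  call <- combine_evidence(list(r_male = 0.5, r_female = 0.55),
                           list(comb_detected = TRUE, comb_confidence = 0.9))
  expect_equal(call$sex, "male")
  # no comb, clear luminance margin -> female
  call2 <- combine_evidence(lum_f,
                            list(comb_detected = FALSE, comb_confidence = 0))
  expect_equal(call2$sex, "female")
  # tiny margin, no comb -> unknown
  call3 <- combine_evidence(list(r_male = 0.5, r_female = 0.51),
                            list(comb_detected = FALSE, comb_confidence = 0))
  expect_equal(call3$sex, "unknown")
  # absence of a comb plus a modest female margin still calls female
  call4 <- combine_evidence(list(r_male = 0.45, r_female = 0.55),
                            list(comb_detected = FALSE, comb_confidence = 0))
  expect_equal(call4$sex, "female")
})

test_that("luminance alone sexes both fixtures correctly", {
  tpl <- sex_templates()
  for (nm in c("male", "female")) {
    fx <- fw_fixture(nm)
    bright <- select_brightest_red_frame(fx$stack, fx$bm)
    prof <- abdominal_profile(fx$stack$red_frames[[bright]],
                              fx$bm$labels == 3)
    lum <- correlate_templates(prof, tpl$male, tpl$female)
    call <- combine_evidence(lum, list(comb_detected = FALSE,
                                       comb_confidence = 0))
    expect_equal(call$sex, nm)
  }
})
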