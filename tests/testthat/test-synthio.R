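# Generator: determinism, ground-truth self-consistency, population model.

test_that("sampling is deterministic and sex-consistent", {
  a <- sample_fly(1)
  b <- sample_fly(1)
  expect_identical(a, b)
  expect_true(sample_fly(5, sex = "male")$sexcomb_present)
  expect_false(sample_fly(5, sex = "female")$sexcomb_present)
  for (s in 11:25) {
    fly <- sample_fly(s)
    expect_identical(fly$sexcomb_present, fly$sex == "male")
  }
})

test_that("trait distributions follow the population parameters", {
  wl <- vapply(seq_len(1000), function(i)
    sample_fly(10000 + i, sex = "female")$wl_px, numeric(1))
  expect_gt(mean(wl), 99)
  expect_lt(mean(wl), 101)
  expect_gt(stats::sd(wl), 4)
  expect_lt(stats::sd(wl), 6)
  # sex ratio within binomial 99% bounds of 0.5 at n = 200
  sexes <- vapply(seq_len(200), function(i) sample_fly(40000 + i)$sex,
                  character(1))
  n_male <- sum(sexes == "male")
  bounds <- stats::qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_male, bounds[1])
  expect_lte(n_male, bounds[2])
})

test_that("ground-truth geometry is self-consistent", {
  for (s in c(2, 9, 31)) {
    fly <- sample_fly(s)
    areas <- c(fly$head$a * fly$head$b, fly$thorax$a * fly$thorax$b,
               fly$abdomen$a * fly$abdomen$b) * pi
    expect_true(all(diff(areas) > 0))   # head < thorax < abdomen
    # wl equals hinge -> outline-L3 distance of the generating geometry
    w <- fly$wings$right
    d <- sqrt(sum((w$anchors["L3", ] - w$hinge)^2))
    expect_equal(d, fly$wl_px, tolerance = 1e-9)
    # ww matches the anchor pair
    d2 <- sqrt(sum((w$anchors["L2", ] - w$anchors["L5", ])^2))
    expect_equal(d2, fly$ww_px, tolerance = 1e-9)
    # polygon area is within 0.5% of a finer-sampled shoelace evaluation
    canon <- flywalk:::canonical_wing(fly$wing$aspect, fly$wing$vein_angles,
                                      fly$wing$bumps)
    fine <- flywalk:::wing_to_body(canon$outline_fun(
      2 * pi * seq(0, 1 - 1 / 2048, length.out = 2048)),
      fly$wing$hinge, fly$wing$phi, fly$wing$wl, 1)
    expect_equal(fly$wa_px2, flywalk:::shoelace_area(fine),
                 tolerance = 0.005)
  }
})

test_that("rendering is bit-reproducible and respects bounds", {
  truth <- sample_fly(7, sex = "male")
  cfg <- render_config(n_frames = 2, seed = 99)
  s1 <- render_sequence(truth, cfg)
  s2 <- render_sequence(truth, cfg)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$background, s2$background)
  # 8-bit quantization: every value on the k/255 grid
  v <- s1$frames[[1]]$blue[1:100]
  expect_equal(v, round(v * 255) / 255)
  # too small a field of view for the fly is a rendering error
  expect_error(render_sequence(truth, render_config(width = 150, height = 200,
                                                    n_frames = 1)),
               "exceeds image bounds")
})

test_that("render_population produces the requested flies and truth table", {
  cfg <- render_config(n_frames = 1, seed = 5)
  pop <- render_population(4, seed = 7, cfg)
  expect_length(pop$sequences, 4)
  expect_equal(nrow(pop$truth), 4)
  expect_named(pop$truth,
               c("fly_id", "sex", "iod_px", "sw_px", "wl_px", "ww_px",
                 "wa_px2", "body_length_px", "sexcomb_present", "seed"))
  females <- render_population(3, seed = 8, cfg, sex = "female")
  expect_false(any(females$truth$sexcomb_present))
})
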