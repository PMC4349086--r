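# Agreement statistics: Pearson, bi-square IRLS, percent residuals,
# boxplot summaries.

test_that("pearson_r matches the textbook formula", {
  x <- 1:20
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(4)
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), brute, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 10), a[1:10]), "constant")
})

test_that("bisquare regression is exact without noise and robust to one
           gross outlier", {
  x <- seq(1, 10, length.out = 100)
  y <- 2 * x + 1
  fit <- bisquare_regression(x, y)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_true(fit$converged)
  # one point displaced by ~100 residual SDs barely moves the slope
  set.seed(11)
  y2 <- 2 * x + 1 + stats::rnorm(100, 0, 0.05)
  y2[50] <- y2[50] + 50
  fit2 <- bisquare_regression(x, y2)
  expect_lt(abs(fit2$slope - 2), 0.01)
  expect_lt(fit2$weights[50], 1e-6)       # outlier weight driven to zero
  expect_true(all(fit2$weights >= 0 & fit2$weights <= 1))
  expect_error(bisquare_regression(rep(2, 10), 1:10), "constant")
})

test_that("bisquare agrees with OLS when the noise is clean Gaussian", {
  set.seed(21)
  x <- stats::runif(200, 0, 10)
  y <- 3 * x - 2 + stats::rnorm(200, 0, 0.5)
  fit <- bisquare_regression(x, y)
  ols <- stats::lm(y ~ x)
  se <- summary(ols)$coefficients["x", "Std. Error"]
  expect_lt(abs(fit$slope - stats::coef(ols)[2]), 2 * se)
})

test_that("percent residuals follow their definition", {
  x <- c(10, 20, 40)
  fit <- list(slope = 2, intercept = 1)
  y_on <- 2 * x + 1
  expect_equal(percent_residuals(x, y_on, fit), c(0, 0, 0))
  y_off <- y_on + 0.02 * x
  expect_equal(percent_residuals(x, y_off, fit), c(2, 2, 2))
  expect_error(percent_residuals(c(-1, 2), c(1, 2), fit), "positive")
  # residuals of the fit's own predictions are identically zero
  set.seed(2)
  xs <- stats::runif(50, 5, 20); ys <- 1.5 * xs + stats::rnorm(50)
  f <- bisquare_regression(xs, ys)
  expect_equal(percent_residuals(xs, f$slope * xs + f$intercept, f),
               rep(0, 50), tolerance = 1e-10)
  # raw mode
  expect_equal(percent_residuals(c(100), c(103), raw = TRUE), 3)
})

test_that("residual SD recovers an injected 1.5% error at n = 147", {
  set.seed(147)
  manual <- stats::rnorm(147, 100, 8)
  auto <- manual * (1 + stats::rnorm(147, 0, 0.015))
  rep <- agreement_report(manual, auto, trait = "wl")
  expect_gt(rep$sd_pct, 1.2)
  expect_lt(rep$sd_pct, 1.8)
  expect_gt(rep$r, 0.97)
})

test_that("boxplot summaries use type-7 quartiles and the 1.5 rule", {
  b <- boxplot_stats(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$q25, 25.75)
  expect_equal(b$q75, 75.25)
  expect_length(b$outliers, 0)
  set.seed(8)
  sym <- stats::rnorm(500)
  bs <- boxplot_stats(sym)
  expect_lt(abs(bs$median - mean(sym)), 0.2)
  # a point beyond 1.5 box-widths is an outlier; just inside is not
  vals <- c(stats::runif(50, -1, 1))
  q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
  width <- q[2] - q[1]
  inside <- c(vals, q[2] + 1.4 * width)
  outside <- c(vals, q[2] + 2 * width)
  expect_length(boxplot_stats(inside)$outliers, 0)
  expect_gte(length(boxplot_stats(outside)$outliers), 1)
  expect_error(boxplot_stats(c(1, 2, 3)))
})

test_that("validate_measurements reports one row per trait", {
  set.seed(5)
  man <- data.frame(fly_id = 1:60, wl = stats::rnorm(60, 100, 5))
  man$ww <- man$wl * 0.44 + stats::rnorm(60, 0, 1)
  auto <- data.frame(fly_id = 1:60,
                     wl = man$wl * (1 + stats::rnorm(60, 0, 0.01)),
                     ww = man$ww * (1 + stats::rnorm(60, 0, 0.02)))
  rep <- validate_measurements(man, auto, traits = c("wl", "ww"))
  expect_equal(rep$trait, c("wl", "ww"))
  expect_true(all(rep$r > 0.9))
  expect_equal(rep$n, c(60, 60))
})
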