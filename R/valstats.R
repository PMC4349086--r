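# Agreement statistics between manual and automated measurements: Pearson
# correlation, Tukey bi-square robust linear regression, residuals in
# percent of the manual value, and boxplot summaries with the 1.5
# box-width outlier rule.

#' Pearson correlation
#'
#' Sample Pearson correlation coefficient; constant input is an error.
#'
#' @param x,y numeric vectors, length >= 3.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) {
    stop("constant input: correlation undefined")
  }
  stats::cor(x, y)
}

#' Bi-square (Tukey biweight) robust linear regression
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' `w = (1 - (r / (c s))^2)^2` for `|r| < c s`, zero beyond, with tuning
#' constant `c = 4.685` and scale `s = median(|r|) / 0.6745` recomputed
#' from the residuals at every iteration. Converges when the coefficients
#' change by less than `tol` or after `max_iter` iterations (flagged).
#'
#' @param x,y numeric vectors (n >= 3); x must not be constant.
#' @param c_tuning bisquare tuning constant.
#' @param max_iter,tol IRLS stopping rule.
#' @return object of class `bisquare_fit`: `slope`, `intercept`, `weights`,
#'   `converged`, `iterations`, `scale`.
#' @export
bisquare_regression <- function(x, y, c_tuning = 4.685, max_iter = 50,
                                tol = 1e-8) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) < 1e-300) stop("constant x: regression undefined")
  X <- cbind(1, x)
  beta <- stats::coef(stats::lm.fit(X, y))
  w <- rep(1, length(x))
  converged <- FALSE
  scale <- NA_real_
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    # MAD about zero (the regression already carries an intercept); robust
    # even when the initial least-squares fit is dragged by gross outliers
    scale <- stats::median(abs(r)) / 0.6745
    if (scale < 1e-12) {
      # (near-)exact fit: done
      converged <- TRUE
      w <- as.numeric(abs(r) < 1e-8 * (1 + max(abs(y))))
      break
    }
    u <- as.vector(r) / (c_tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2) {
      converged <- FALSE
      break
    }
    fit <- stats::lm.wfit(X, y, w = w)
    beta_new <- stats::coef(fit)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 weights = as.vector(w), converged = converged,
                 iterations = it, scale = scale),
            class = "bisquare_fit")
}

#' @export
print.bisquare_fit <- function(x, ...) {
  cat(sprintf("<bisquare_fit> y = %.4f x + %.4f  (%s, %d iterations)\n",
              x$slope, x$intercept,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Residuals in percent of the manual value
#'
#' The relative error of the automated method: for each pair,
#' `100 * (y_i - (slope * x_i + intercept)) / x_i`, with `x` the manual and
#' `y` the automated measurement. `raw = TRUE` skips the fit and uses
#' `100 * (y - x) / x` instead.
#'
#' @param x manual values (> 0).
#' @param y automated values.
#' @param fit a `bisquare_fit` (ignored when `raw = TRUE`).
#' @param raw use raw differences instead of fit residuals.
#' @return numeric vector of percent residuals.
#' @export
percent_residuals <- function(x, y, fit = NULL, raw = FALSE) {
  if (any(x <= 0)) stop("manual values must be positive")
  if (raw) return(100 * (y - x) / x)
  if (is.null(fit)) fit <- bisquare_regression(x, y)
  100 * (y - (fit$slope * x + fit$intercept)) / x
}

#' Boxplot summary with the 1.5 box-width outlier rule
#'
#' Median and quartiles use the linear-interpolation convention (type 7 of
#' [stats::quantile()]). The box width is the interquartile range; outliers
#' lie more than 1.5 box-widths below the 25th or above the 75th
#' percentile; whiskers sit at the most extreme non-outlier values.
#'
#' @param values numeric vector, n >= 4.
#' @param k outlier multiplier (default 1.5).
#' @return list `(median, q25, q75, whiskers, outliers, outlier_indices)`.
#' @export
boxplot_stats <- function(values, k = 1.5) {
  stopifnot(length(values) >= 4)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  width <- q[3] - q[1]
  lo <- q[1] - k * width
  hi <- q[3] + k * width
  out_idx <- which(values < lo | values > hi)
  inl <- if (length(out_idx)) values[-out_idx] else values
  list(median = q[2], q25 = q[1], q75 = q[3],
       whiskers = c(min(inl), max(inl)),
       outliers = values[out_idx], outlier_indices = out_idx)
}

#' Manual-vs-automated agreement report for one trait
#'
#' Pearson correlation, bi-square robust fit, percent residuals and their
#' distribution summary (mean +/- SD in percent of the manual value,
#' quartiles and outliers per the 1.5 rule).
#'
#' @param manual,auto paired measurement vectors (manual > 0).
#' @param trait trait name carried into the report.
#' @param raw_residuals use raw `(auto - manual)` residuals instead of
#'   fit-based ones.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(manual, auto, trait = "trait",
                             raw_residuals = FALSE) {
  keep <- is.finite(manual) & is.finite(auto)
  manual <- manual[keep]; auto <- auto[keep]
  fit <- bisquare_regression(manual, auto)
  res <- percent_residuals(manual, auto, fit, raw = raw_residuals)
  bx <- boxplot_stats(res)
  structure(list(trait = trait, n = length(manual),
                 r = pearson_r(manual, auto),
                 slope = fit$slope, intercept = fit$intercept, fit = fit,
                 residuals_pct = res,
                 mean_pct = mean(res), sd_pct = stats::sd(res),
                 median_pct = bx$median, q25_pct = bx$q25, q75_pct = bx$q75,
                 outlier_indices = which(keep)[bx$outlier_indices]),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d): R = %.3f, residuals %.2f +/- %.2f%%, median %.2f [%.2f, %.2f]\n",
    x$trait, x$n, x$r, x$mean_pct, x$sd_pct, x$median_pct, x$q25_pct,
    x$q75_pct))
  invisible(x)
}

#' Agreement reports for several traits from paired CSV tables
#'
#' @param manual_df,auto_df data.frames keyed by `fly_id` with one column
#'   per trait.
#' @param traits trait column names (present in both tables).
#' @param raw_residuals see [agreement_report()].
#' @return data.frame with one row per trait (r, slope, intercept, mean,
#'   sd, quartiles, n outliers).
#' @export
validate_measurements <- function(manual_df, auto_df,
                                  traits = c("wl", "ww", "wa", "iod", "sw"),
                                  raw_residuals = FALSE) {
  m <- merge(manual_df, auto_df, by = "fly_id", suffixes = c("_man", "_auto"))
  rows <- lapply(traits, function(tr) {
    rep <- agreement_report(m[[paste0(tr, "_man")]],
                            m[[paste0(tr, "_auto")]],
                            trait = tr, raw_residuals = raw_residuals)
    data.frame(trait = tr, n = rep$n, r = rep$r, slope = rep$slope,
               intercept = rep$intercept, mean_pct = rep$mean_pct,
               sd_pct = rep$sd_pct, median_pct = rep$median_pct,
               q25_pct = rep$q25_pct, q75_pct = rep$q75_pct,
               n_outliers = length(rep$outlier_indices))
  })
  do.call(rbind, rows)
}
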