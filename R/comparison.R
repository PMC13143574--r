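#' Pearson correlation between two index vectors
#'
#' Sample Pearson r with the usual two-sided t-transform p value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{r} and \code{p_value}.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance in one of the inputs")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Range-ratio error ratio for Deming regression
#'
#' The measurement-error standard-deviation ratio used in the index
#' comparison is taken to be the ratio of the observed value ranges, i.e.
#' both indices are assumed to carry the same signal-to-noise ratio:
#' \code{delta = range(db) / range(ce)}. With the study's ranges
#' (Db 1.99, CE 8.12) this gives 0.245..., printed as 0.24.
#'
#' @param db_values,ce_values numeric vectors (or precomputed ranges of
#'   length 1, in which case they are used directly).
#' @return delta, the Db:CE error-SD ratio.
#' @export
error_ratio <- function(db_values, ce_values) {
  rng <- function(v) if (length(v) == 1L) v else diff(range(v))
  r_db <- rng(db_values); r_ce <- rng(ce_values)
  if (r_db <= 0 || r_ce <= 0) stop("degenerate range: zero spread in an index")
  r_db / r_ce
}

deming_slope <- function(x, y, lambda) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sxy == 0) stop("undefined slope: zero covariance between x and y")
  d <- syy - lambda * sxx
  slope <- (d + sqrt(d^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  c(slope = slope, intercept = my - slope * mx)
}

#' Deming (errors-in-variables) regression
#'
#' Symmetric straight-line fit that attributes measurement error to both
#' variables; the geometry is set by \code{delta}, the ratio of the error
#' standard deviations sd(x-error)/sd(y-error); the closed-form solution
#' uses the error variance ratio lambda = sd(y-error)^2/sd(x-error)^2 =
#' 1/delta^2. Unlike ordinary least squares the
#' fit does not depend on which variable is called x: swapping the axes
#' (and inverting delta) inverts the slope exactly. Standard errors and
#' 95\% confidence intervals are leave-one-out jackknife estimates.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param delta error-SD ratio sd(x)/sd(y) (> 0); e.g. from
#'   \code{\link{error_ratio}}.
#' @param conf confidence level for the intervals (default 0.95).
#' @return An object of class \code{deming_fit}: list with \code{slope},
#'   \code{intercept}, \code{se_slope}, \code{se_intercept},
#'   \code{ci_slope}, \code{ci_intercept}, \code{delta}, \code{n}.
#' @export
deming_regression <- function(x, y, delta, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3L, delta > 0)
  n <- length(x)
  lambda <- 1 / delta^2
  est <- deming_slope(x, y, lambda)
  # leave-one-out jackknife
  loo <- vapply(seq_len(n), function(i) deming_slope(x[-i], y[-i], lambda),
                numeric(2L))
  jack_se <- function(theta_i, theta_bar = mean(theta_i)) {
    sqrt((n - 1) / n * sum((theta_i - theta_bar)^2))
  }
  se_slope <- jack_se(loo[1L, ])
  se_intercept <- jack_se(loo[2L, ])
  q <- stats::qt(1 - (1 - conf) / 2, df = n - 2L)
  structure(list(
    slope = unname(est["slope"]), intercept = unname(est["intercept"]),
    se_slope = se_slope, se_intercept = se_intercept,
    ci_slope = unname(est["slope"]) + c(-1, 1) * q * se_slope,
    ci_intercept = unname(est["intercept"]) + c(-1, 1) * q * se_intercept,
    delta = delta, n = n
  ), class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (delta = %.4g, n = %d)\n", x$delta, x$n))
  cat(sprintf("  slope     %8.4f  SE %.4f  95%% CI [%.4f, %.4f]\n",
              x$slope, x$se_slope, x$ci_slope[1L], x$ci_slope[2L]))
  cat(sprintf("  intercept %8.4f  SE %.4f  95%% CI [%.4f, %.4f]\n",
              x$intercept, x$se_intercept, x$ci_intercept[1L], x$ci_intercept[2L]))
  invisible(x)
}

#' Per-site Deming regressions
#'
#' Fits one Deming regression per site label, as a control for spatial
#' structure across forest sites. The error ratio is either computed once
#' from all rows (\code{"global"}, the default) or recomputed within each
#' site (\code{"per-group"}). Sites with fewer than 3 rows are skipped
#' with a warning.
#'
#' @param table data frame with columns \code{site}, \code{db}, \code{ce}.
#' @param delta_policy \code{"global"} or \code{"per-group"}.
#' @return named list of \code{deming_fit}, one per retained site.
#' @export
per_group_deming <- function(table, delta_policy = c("global", "per-group")) {
  delta_policy <- match.arg(delta_policy)
  stopifnot(all(c("site", "db", "ce") %in% names(table)))
  delta_global <- if (delta_policy == "global") error_ratio(table$db, table$ce) else NA
  fits <- list()
  for (s in unique(table$site)) {
    rows <- table[table$site == s, , drop = FALSE]
    if (nrow(rows) < 3L) {
      warning("site '", s, "' has fewer than 3 rows; skipped", call. = FALSE)
      next
    }
    d <- if (delta_policy == "global") delta_global else error_ratio(rows$db, rows$ce)
    fits[[as.character(s)]] <- deming_regression(rows$db, rows$ce, d)
  }
  fits
}

#' Zero-intercept power-law fit of runtime against cloud size
#'
#' Fits t = a * N^b by nonlinear least squares on the original scale
#' (no intercept: computation time vanishes as N goes to 0), initialized
#' from the log-log ordinary least squares fit. Reports the coefficients,
#' their standard errors, and R-squared on the original scale.
#'
#' @param t computation times in seconds (> 0).
#' @param n cloud sizes in points (> 0).
#' @return An object of class \code{scaling_fit}: list with \code{a},
#'   \code{b}, \code{se_a}, \code{se_b}, \code{r_squared}.
#' @export
fit_power_scaling <- function(t, n) {
  stopifnot(length(t) == length(n), length(t) >= 3L, all(t > 0), all(n > 0))
  init <- stats::lm(log(t) ~ log(n))
  start <- list(a = exp(unname(stats::coef(init)[1L])),
                b = unname(stats::coef(init)[2L]))
  dat <- data.frame(t = t, n = n)
  fit <- tryCatch(
    minpack.lm::nlsLM(t ~ a * n^b, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      cond <- simpleError(paste0("power-law fit did not converge: ",
                                 conditionMessage(e)))
      cond$loglog_fallback <- start
      stop(cond)
    })
  co <- summary(fit)$coefficients
  resid <- dat$t - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((dat$t - mean(dat$t))^2)
  structure(list(a = co["a", "Estimate"], b = co["b", "Estimate"],
                 se_a = co["a", "Std. Error"], se_b = co["b", "Std. Error"],
                 r_squared = r2),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Power-law scaling t = a*N^b: a = %.4g (SE %.2g), b = %.4f (SE %.2g), R^2 = %.3f\n",
              x$a, x$se_a, x$b, x$se_b, x$r_squared))
  invisible(x)
}
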