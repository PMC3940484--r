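# Correlation statistics: Pearson correlations on log10 abundances, the
# test for comparing two dependent (overlapping) correlations sharing one
# variable, and prediction-band width summaries.

#' Pearson correlation of paired log10 abundances
#'
#' @param x_abundances,y_abundances paired numeric vectors (log10 scale;
#'   transform upstream).
#' @return the Pearson correlation coefficient.
#' @export
pearson_log <- function(x_abundances, y_abundances) {
  check_finite_vector(x_abundances, "x_abundances", 3L)
  check_finite_vector(y_abundances, "y_abundances", 3L)
  if (length(x_abundances) != length(y_abundances))
    stop("'x_abundances' and 'y_abundances' must be paired", call. = FALSE)
  if (sd(x_abundances) == 0 || sd(y_abundances) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  cor(x_abundances, y_abundances)
}

#' Compare two dependent correlations sharing one variable
#'
#' Tests H0: rho1 = rho2 where `r1 = cor(x, y1)` and `r2 = cor(x, y2)`
#' share the variable `x` and `r12 = cor(y1, y2)`, assuming an underlying
#' multivariate Gaussian.  Uses the Fisher-z statistic for overlapping
#' correlations of Meng, Rosenthal and Rubin (1992):
#' \deqn{z = (z_1 - z_2)\sqrt{\frac{n - 3}{2 (1 - r_{12}) h}}}
#' with \eqn{h = (1 - f \bar{r}^2) / (1 - \bar{r}^2)},
#' \eqn{f = \min\{(1 - r_{12}) / (2 (1 - \bar{r}^2)), 1\}} and
#' \eqn{\bar{r}^2 = (r_1^2 + r_2^2) / 2}.
#'
#' @param r1,r2 the two correlations with the shared variable.
#' @param r12 the correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return list of class `"correlation_comparison"` with `r1`, `r2`, `r12`,
#'   `n`, `z` and two-sided `p_two_sided`.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n) {
  for (nm in c("r1", "r2", "r12")) {
    r <- check_number(get(nm), nm)
    if (abs(r) > 1)
      stop(sprintf("'%s' must lie in [-1, 1]", nm), call. = FALSE)
    if (abs(r) == 1)
      stop(sprintf("'%s' is +/-1: the Fisher transform diverges", nm),
           call. = FALSE)
  }
  check_number(n, "n", min = 4)
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r12) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  structure(list(r1 = r1, r2 = r2, r12 = r12, n = n, z = z,
                 p_two_sided = 2 * pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("Dependent-correlation test: r1 = %.3f vs r2 = %.3f (r12 = %.3f, n = %d)\n",
              x$r1, x$r2, x$r12, as.integer(x$n)))
  cat(sprintf("  z = %.3f, two-sided p = %.3g\n", x$z, x$p_two_sided))
  invisible(x)
}

#' Prediction-band width of a log-log regression
#'
#' Fits `y ~ x` by OLS and reports the full width of the Gaussian
#' prediction interval for a new observation at the covariate mean (the
#' band's narrowest point), together with its unlogged fold range
#' \eqn{10^{width}}.
#'
#' @param x,y paired numeric vectors on the log10 scale (>= 10 pairs).
#' @param level coverage of the band (e.g. 0.50 or 0.95).
#' @return list of class `"prediction_band"` with `level`,
#'   `width_log10_at_center` and `fold_range`.
#' @export
prediction_band <- function(x, y, level = 0.95) {
  check_finite_vector(x, "x", 10L)
  check_finite_vector(y, "y", 10L)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired",
                                   call. = FALSE)
  check_number(level, "level", min = 0)
  if (level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  fit <- ols_fit(x, y)
  n <- fit$n
  sigma <- sqrt(fit$rss / (n - 2))
  half <- qt((1 + level) / 2, df = n - 2) * sigma * sqrt(1 + 1 / n)
  structure(list(level = level, width_log10_at_center = 2 * half,
                 fold_range = 10^(2 * half)),
            class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf("%d%% prediction band: width %.3f log10 (%.1f-fold unlogged)\n",
              round(100 * x$level), x$width_log10_at_center, x$fold_range))
  invisible(x)
}
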