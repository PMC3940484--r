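# Comparison of measured (ribosome-profiling) and inferred
# translation-rate distributions.  All comparisons are scale-free:
# variances, fold ranges and correlations are computed on log10 rates.

rates_of <- function(x, name = "rates") {
  r <- if (inherits(x, "translation_rate_set") || is.data.frame(x)) x$rate
       else x
  if (!length(r) || !all(is.finite(r)) || any(r <= 0))
    stop(sprintf("'%s' must be non-empty, finite and > 0", name),
         call. = FALSE)
  r
}

#' Scale a rate set proportionally to a target median
#'
#' Multiplies every rate by `target_median / median(rates)`.  On the log10
#' scale this is a pure shift, so all ratio-based statistics (fold ranges,
#' log-variances, correlations) are unchanged.
#'
#' @param rates a [translation_rate_set()], data.frame with a `rate`
#'   column, or positive numeric vector.
#' @param target_median target median on the linear scale (> 0).
#' @return object of the same shape with scaled rates.
#' @export
scale_to_median <- function(rates, target_median) {
  check_number(target_median, "target_median")
  if (target_median <= 0)
    stop("'target_median' must be positive", call. = FALSE)
  r <- rates_of(rates)
  fac <- target_median / median(r)
  if (is.data.frame(rates)) {
    rates$rate <- rates$rate * fac
    rates
  } else rates * fac
}

#' Central fold range of a rate distribution
#'
#' Ratio of the upper to the lower empirical quantile bounding the central
#' `coverage` mass (2.5th to 97.5th percentile by default).  Quantiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param rates positive rates (vector, data.frame or
#'   [translation_rate_set()]).
#' @param coverage central mass covered (default 0.95).
#' @return the fold range (linear scale, >= 1).
#' @export
central_fold_range <- function(rates, coverage = 0.95) {
  check_number(coverage, "coverage", min = 0)
  if (coverage >= 1) stop("'coverage' must be in (0, 1)", call. = FALSE)
  r <- rates_of(rates)
  n_min <- ceiling(2 / (1 - coverage))
  if (length(r) < n_min)
    stop(sprintf("need >= %d values for coverage %.2f", n_min, coverage),
         call. = FALSE)
  q <- quantile(r, c((1 - coverage) / 2, (1 + coverage) / 2), names = FALSE)
  q[2] / q[1]
}

#' Intersect two rate sets and compare their spreads
#'
#' Restricts both sets to the shared gene identifiers, then reports the
#' ratio of log10 variances (measured over inferred) and the coefficient
#' of determination of the OLS fit of one set of log10 rates on the other.
#'
#' @param measured,inferred [translation_rate_set()]s (or data.frames with
#'   `gene_id` and `rate`).
#' @return list with `n_common`, `variance_ratio_log10`
#'   (var(log10 measured) / var(log10 inferred)), `r_squared`,
#'   `var_measured_log10` and `var_inferred_log10`.
#' @export
intersect_and_compare <- function(measured, inferred) {
  common <- intersect(measured$gene_id, inferred$gene_id)
  if (length(common) < 10)
    stop("fewer than 10 shared gene identifiers", call. = FALSE)
  lm10 <- log10(measured$rate[match(common, measured$gene_id)])
  li10 <- log10(inferred$rate[match(common, inferred$gene_id)])
  vm <- var(lm10); vi <- var(li10)
  if (vi == 0 || vm == 0)
    stop("zero variance in a rate set on the intersection", call. = FALSE)
  list(n_common = length(common), variance_ratio_log10 = vm / vi,
       r_squared = cor(lm10, li10)^2,
       var_measured_log10 = vm, var_inferred_log10 = vi)
}

#' Adjust a subset variance to a superset
#'
#' Rescales a variance estimated on an intersection of genes to the full
#' gene set of a reference source, by the ratio of the reference
#' variances on the superset and on the subset:
#' `adjusted = subset_var * var_inferred_superset / var_inferred_subset`.
#'
#' @param subset_var variance measured on the intersection.
#' @param var_inferred_subset reference (inferred-rate) variance on the
#'   same intersection.
#' @param var_inferred_superset reference variance on the full set.
#' @return the adjusted variance.
#' @export
adjust_variance_to_superset <- function(subset_var, var_inferred_subset,
                                        var_inferred_superset) {
  check_number(subset_var, "subset_var", min = 0)
  check_number(var_inferred_subset, "var_inferred_subset")
  check_number(var_inferred_superset, "var_inferred_superset", min = 0)
  if (var_inferred_subset <= 0)
    stop("'var_inferred_subset' must be positive", call. = FALSE)
  subset_var * var_inferred_superset / var_inferred_subset
}

#' Density table of log10 rates for plotting
#'
#' Histogram of log10 rates with frequencies normalised to sum to one,
#' suitable for overlaying distributions from different sources.
#'
#' @param rates positive rates.
#' @param breaks number of bins or a vector of log10 break points.
#' @return data.frame with `log10_rate` (bin midpoints) and `frequency`.
#' @export
rate_density_table <- function(rates, breaks = 50) {
  r <- log10(rates_of(rates))
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  data.frame(log10_rate = h$mids, frequency = h$counts / sum(h$counts))
}
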