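# Two-part (change-point) log-log calibration of survey protein abundances
# against gold-standard individual measurements.

#' Construct a table of calibration pairs
#'
#' A calibration pair joins, for one gene, a gold-standard individual
#' abundance measurement (e.g. SILAC or quantitative western blot) with the
#' abundance reported for the same protein by a whole-proteome survey.
#' Both are stored on the log10 molecules-per-cell scale.
#'
#' @param gene_id character vector of gene identifiers.
#' @param reference_log10 gold-standard abundances, log10 molecules/cell.
#' @param survey_log10 survey abundances, log10 molecules/cell.
#' @param method_tag optional free-text label of the reference method.
#' @return a `data.frame` of class `"calibration_pairs"`.
#' @export
calibration_pairs <- function(gene_id, reference_log10, survey_log10,
                              method_tag = NA_character_) {
  n <- length(reference_log10)
  check_finite_vector(reference_log10, "reference_log10")
  check_finite_vector(survey_log10, "survey_log10")
  if (length(survey_log10) != n)
    stop("'reference_log10' and 'survey_log10' must have equal length",
         call. = FALSE)
  out <- data.frame(gene_id = as.character(gene_id),
                    reference_log10 = as.numeric(reference_log10),
                    survey_log10 = as.numeric(survey_log10),
                    method_tag = rep_len(as.character(method_tag), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("calibration_pairs", "data.frame")
  out
}

as_pair_matrix <- function(pairs) {
  if (is.data.frame(pairs)) {
    need <- c("reference_log10", "survey_log10")
    miss <- setdiff(need, names(pairs))
    if (length(miss))
      stop("calibration pairs lack column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- pairs$survey_log10
    y <- pairs$reference_log10
  } else stop("'pairs' must be a data.frame of calibration pairs",
              call. = FALSE)
  check_finite_vector(x, "survey_log10")
  check_finite_vector(y, "reference_log10")
  list(x = x, y = y)
}

#' Fit a single calibration line with leave-one-out cross-validation
#'
#' Ordinary least squares of the gold-standard abundance on the survey
#' abundance (both log10).  The leave-one-out root-mean-square prediction
#' error is computed exactly via the PRESS identity
#' \eqn{e_{(i)} = e_i / (1 - h_{ii})}.
#'
#' @param pairs calibration pairs, see [calibration_pairs()].
#' @return list with `slope`, `intercept`, `cv_rmse`, `rss`, `sigma`
#'   (residual standard deviation, denominator n - 2) and `n`.
#' @export
fit_single_line <- function(pairs) {
  d <- as_pair_matrix(pairs)
  n <- length(d$x)
  if (n < 3) stop("at least 3 calibration pairs are required", call. = FALSE)
  fit <- ols_fit(d$x, d$y)
  press <- fit$residuals / (1 - fit$hat)
  list(slope = fit$slope, intercept = fit$intercept,
       cv_rmse = sqrt(mean(press^2)), rss = fit$rss,
       sigma = sqrt(fit$rss / (n - 2)), n = n)
}

#' Construct a two-part calibration model
#'
#' Represents the piecewise-linear (two segment) log-log map from survey
#' abundance to calibrated abundance.  The two segments are fitted
#' independently (no continuity constraint); a survey value equal to the
#' change point is assigned to the upper segment.
#'
#' @param changepoint_log10 survey abundance at the split (log10).
#' @param lower_slope,lower_intercept segment for survey < change point.
#' @param upper_slope,upper_intercept segment for survey >= change point.
#' @param cv_rmse,single_slope,single_intercept,single_cv_rmse,lrt_pvalue
#'   optional diagnostics attached by [fit_segmented()] / [bootstrap_lrt()].
#' @return object of class `"segmented_model"`.
#' @export
segmented_model <- function(changepoint_log10, lower_slope, lower_intercept,
                            upper_slope, upper_intercept, cv_rmse = NA_real_,
                            single_slope = NA_real_,
                            single_intercept = NA_real_,
                            single_cv_rmse = NA_real_,
                            lrt_pvalue = NA_real_) {
  for (nm in c("changepoint_log10", "lower_slope", "lower_intercept",
               "upper_slope", "upper_intercept"))
    check_number(get(nm), nm)
  structure(list(changepoint_log10 = changepoint_log10,
                 lower_slope = lower_slope, lower_intercept = lower_intercept,
                 upper_slope = upper_slope, upper_intercept = upper_intercept,
                 cv_rmse = cv_rmse, single_slope = single_slope,
                 single_intercept = single_intercept,
                 single_cv_rmse = single_cv_rmse, lrt_pvalue = lrt_pvalue),
            class = "segmented_model")
}

#' @export
print.segmented_model <- function(x, ...) {
  cat("Two-part calibration model (log10 molecules/cell)\n")
  cat(sprintf("  change point : 10^%.3f\n", x$changepoint_log10))
  cat(sprintf("  below        : slope %.3f, intercept %.3f\n",
              x$lower_slope, x$lower_intercept))
  cat(sprintf("  above        : slope %.3f, intercept %.3f\n",
              x$upper_slope, x$upper_intercept))
  if (is.finite(x$cv_rmse))
    cat(sprintf("  LOOCV RMSE   : %.4f (single line: %.4f)\n",
                x$cv_rmse, x$single_cv_rmse))
  if (is.finite(x$lrt_pvalue))
    cat(sprintf("  bootstrap LRT p-value vs single line: %.4g\n",
                x$lrt_pvalue))
  invisible(x)
}

# Candidate change points: every observed survey value plus a uniform grid
# in 0.05 log10 steps across the observed range.
default_changepoint_grid <- function(x, step = 0.05) {
  r <- range(x)
  sort(unique(c(x, seq(r[1], r[2], by = step))))
}

# Piecewise LOOCV RMSE for one candidate change point.  Points below the
# candidate form the lower segment, points at or above it the upper one.
# Returns +Inf when either segment cannot support a held-out refit
# (fewer than 3 points, or no predictor spread).
seg_cv_rmse <- function(x, y, cp) {
  lower <- x < cp
  n_lo <- sum(lower); n_up <- sum(!lower)
  if (n_lo < 2 || n_up < 2) return(Inf)
  press <- numeric(length(x))
  for (side in list(lower, !lower)) {
    xs <- x[side]; ys <- y[side]
    if (length(unique(xs)) < 2) return(Inf)
    fit <- ols_fit(xs, ys)
    if (any(fit$hat >= 1 - 1e-12)) return(Inf)
    press[side] <- fit$residuals / (1 - fit$hat)
  }
  sqrt(mean(press^2))
}

#' Fit a two-part calibration with cross-validated change-point selection
#'
#' For every candidate change point, two independent OLS lines are fitted
#' to the pairs below and at-or-above the candidate, and the leave-one-out
#' cross-validated RMSE of the piecewise model is computed (each held-out
#' point is predicted from a refit of its own segment).  The candidate
#' minimising the LOOCV RMSE is selected; ties are broken toward the
#' candidate nearest the median survey abundance.  The single-line
#' alternative is fitted alongside and attached for comparison.
#'
#' Candidates with fewer than two pairs strictly on either side are
#' skipped; candidates whose LOOCV cannot be evaluated (a two-point
#' segment, which any deletion degenerates) are never selected.
#'
#' @param pairs calibration pairs, see [calibration_pairs()].
#' @param changepoint_grid optional numeric vector of candidate change
#'   points; defaults to all observed survey values plus a 0.05 log10 grid.
#' @return a [segmented_model()] with `cv_rmse`, the single-line
#'   alternative, and attributes `grid` / `grid_cv_rmse` holding the full
#'   model-selection curve.
#' @export
fit_segmented <- function(pairs, changepoint_grid = NULL) {
  d <- as_pair_matrix(pairs)
  x <- d$x; y <- d$y
  if (length(x) < 6)
    stop("at least 6 calibration pairs are required for a two-part fit",
         call. = FALSE)
  grid <- if (is.null(changepoint_grid)) default_changepoint_grid(x)
          else sort(unique(changepoint_grid))
  admissible <- vapply(grid, function(cp)
    sum(x < cp) >= 2 && sum(x > cp) >= 2, logical(1))
  if (!any(admissible))
    stop("no admissible change-point candidate (need >= 2 pairs strictly ",
         "on each side)", call. = FALSE)
  cv <- rep(Inf, length(grid))
  cv[admissible] <- vapply(grid[admissible],
                           function(cp) seg_cv_rmse(x, y, cp), numeric(1))
  if (!any(is.finite(cv)))
    stop("no change-point candidate admits a cross-validated two-part fit",
         call. = FALSE)
  best_cv <- min(cv)
  tied <- which(cv <= best_cv + 1e-12)
  cp <- grid[tied[which.min(abs(grid[tied] - median(x)))]]

  lo <- ols_fit(x[x < cp], y[x < cp])
  up <- ols_fit(x[x >= cp], y[x >= cp])
  single <- fit_single_line(pairs)
  out <- segmented_model(cp, lo$slope, lo$intercept, up$slope, up$intercept,
                         cv_rmse = best_cv, single_slope = single$slope,
                         single_intercept = single$intercept,
                         single_cv_rmse = single$cv_rmse)
  attr(out, "grid") <- grid
  attr(out, "grid_cv_rmse") <- cv
  out
}

# Profiled residual sum of squares of the best two-part model, minimised
# over all admissible splits of the sorted data.  O(n + number of splits)
# via prefix sums; used by the bootstrap where only the likelihood matters.
seg_profile_rss <- function(x_sorted, y, splits = NULL) {
  n <- length(x_sorted)
  if (is.null(splits)) splits <- seg_profile_splits(x_sorted)
  if (!length(splits)) return(Inf)
  cx <- cumsum(x_sorted); cy <- cumsum(y)
  cxx <- cumsum(x_sorted^2); cyy <- cumsum(y^2); cxy <- cumsum(x_sorted * y)
  rss_part <- function(sx, sy, sxx, syy, sxy, m) {
    sxx_c <- sxx - sx^2 / m
    syy_c <- syy - sy^2 / m
    sxy_c <- sxy - sx * sy / m
    ifelse(sxx_c > 1e-12, pmax(syy_c - sxy_c^2 / sxx_c, 0), Inf)
  }
  k <- splits
  lower <- rss_part(cx[k], cy[k], cxx[k], cyy[k], cxy[k], k)
  upper <- rss_part(cx[n] - cx[k], cy[n] - cy[k], cxx[n] - cxx[k],
                    cyy[n] - cyy[k], cxy[n] - cxy[k], n - k)
  min(lower + upper)
}

# Admissible split sizes: >= 2 points on each side and a strict gap in x
# (so that a change point can sit between the two segments).
seg_profile_splits <- function(x_sorted) {
  n <- length(x_sorted)
  k <- 2:(n - 2)
  k[x_sorted[k] < x_sorted[k + 1] - 1e-12]
}

#' Bootstrap likelihood-ratio test of two-part versus single-line fit
#'
#' The observed statistic is \eqn{n \log(RSS_1 / RSS_2)}, where
#' \eqn{RSS_1} is the residual sum of squares of the single line and
#' \eqn{RSS_2} that of the best two-part model with the change point
#' profiled out (minimised over all admissible splits).  The null
#' distribution is obtained by a parametric bootstrap: responses are
#' simulated from the fitted single line with Gaussian residual standard
#' deviation, and both models are refitted to each replicate.  The p-value
#' uses the standard (1 + exceedances) / (n_boot + 1) estimator.
#'
#' @param pairs calibration pairs.
#' @param n_boot number of bootstrap replicates (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @return list with `p_value`, `statistic`, `n_boot`.
#' @export
bootstrap_lrt <- function(pairs, n_boot = 999, seed = NULL) {
  if (n_boot < 99) stop("'n_boot' must be at least 99", call. = FALSE)
  d <- as_pair_matrix(pairs)
  ord <- order(d$x)
  x <- d$x[ord]; y <- d$y[ord]
  n <- length(x)
  if (n < 6) stop("too few pairs for the bootstrap test", call. = FALSE)
  splits <- seg_profile_splits(x)
  if (!length(splits))
    stop("degenerate survey values: no admissible two-part split",
         call. = FALSE)
  single <- ols_fit(x, y)
  rss2 <- seg_profile_rss(x, y, splits)
  if (!is.finite(rss2) || rss2 <= 0) rss2 <- .Machine$double.eps * single$rss
  stat_obs <- n * log(single$rss / rss2)
  sigma0 <- sqrt(single$rss / (n - 2))
  stat_null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yb <- single$fitted + rnorm(n, 0, sigma0)
      f0 <- ols_fit(x, yb)
      r2 <- seg_profile_rss(x, yb, splits)
      n * log(f0$rss / r2)
    }, numeric(1))
  })
  p <- (1 + sum(stat_null >= stat_obs)) / (n_boot + 1)
  list(p_value = p, statistic = stat_obs, n_boot = n_boot)
}

#' Apply a two-part calibration to survey abundances
#'
#' Each log10 survey value is mapped through the segment that contains it
#' (values at or above the change point use the upper segment).  Values are
#' not clamped: outside the calibration span the nearest segment
#' extrapolates.
#'
#' @param model a [segmented_model()].
#' @param survey_log10 numeric vector, log10 molecules/cell.
#' @return corrected abundances, log10 molecules/cell.
#' @export
apply_correction <- function(model, survey_log10) {
  stopifnot(inherits(model, "segmented_model"))
  check_finite_vector(survey_log10, "survey_log10")
  ifelse(survey_log10 < model$changepoint_log10,
         model$lower_intercept + model$lower_slope * survey_log10,
         model$upper_intercept + model$upper_slope * survey_log10)
}

#' @export
predict.segmented_model <- function(object, newdata, ...) {
  apply_correction(object, newdata)
}

#' Invert a two-part calibration
#'
#' Maps calibrated (reference-scale) abundances back to the survey scale.
#' Requires strictly positive slopes.  The inverse of the lower segment is
#' used when it lands below the change point, otherwise the inverse of the
#' upper segment; for a (near-)continuous model this reproduces the
#' piecewise inverse.
#'
#' @param model a [segmented_model()].
#' @param reference_log10 numeric vector, log10 molecules/cell.
#' @return survey-scale abundances, log10 molecules/cell.
#' @export
invert_correction <- function(model, reference_log10) {
  stopifnot(inherits(model, "segmented_model"))
  if (model$lower_slope <= 0 || model$upper_slope <= 0)
    stop("inversion requires positive segment slopes", call. = FALSE)
  check_finite_vector(reference_log10, "reference_log10")
  x_lo <- (reference_log10 - model$lower_intercept) / model$lower_slope
  x_up <- (reference_log10 - model$upper_intercept) / model$upper_slope
  ifelse(x_lo < model$changepoint_log10, x_lo, x_up)
}

#' Ratio profile of reference to survey abundances
#'
#' Per-pair linear-scale ratios reference/survey together with a locally
#' weighted (lowess) smooth of log10 ratio against log10 survey abundance.
#' After a successful correction the smooth is approximately flat at ratio
#' one.
#'
#' @param pairs calibration pairs.
#' @param model optional [segmented_model()]; when supplied, survey values
#'   are corrected before the ratios are formed.
#' @param f lowess smoothing span (default 1.0).
#' @return list with `pairs` (data.frame `survey_log10`, `ratio`) and
#'   `smooth` (data.frame `survey_log10`, `ratio`), ratios on the linear
#'   scale.
#' @export
bias_ratio_profile <- function(pairs, model = NULL, f = 1.0) {
  d <- as_pair_matrix(pairs)
  if (length(d$x) < 5)
    stop("at least 5 pairs are required for a ratio profile", call. = FALSE)
  denom <- if (is.null(model)) d$x else apply_correction(model, d$x)
  log_ratio <- d$y - denom
  sm <- lowess(d$x, log_ratio, f = f)
  list(pairs = data.frame(survey_log10 = d$x, ratio = 10^log_ratio),
       smooth = data.frame(survey_log10 = sm$x, ratio = 10^sm$y))
}
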