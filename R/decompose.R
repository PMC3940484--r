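# Errors-in-variables decomposition of the variance in protein expression
# into measurement error and the contributions of transcription, mRNA
# degradation, translation and protein degradation, under two independent
# strategies.

#' Pooled within-gene replicate variance (stochastic measurement error)
#'
#' Estimates the stochastic (replicate-to-replicate) measurement-error
#' variance as the pooled within-gene variance
#' \deqn{\hat\sigma^2 = \sum_i \sum_j (x_{ij} - \bar x_i)^2 / \sum_i (J_i - 1)}
#' over genes with at least two non-missing replicates.
#'
#' @param replicate_table numeric matrix or data.frame, one row per gene
#'   and one column per replicate (log10 scale).
#' @return the pooled variance, with attribute `n_genes_used`; genes with
#'   fewer than two replicates are skipped and their count reported via
#'   `message()`.
#' @export
stochastic_error_from_replicates <- function(replicate_table) {
  m <- as.matrix(replicate_table)
  if (!is.numeric(m) || ncol(m) < 2)
    stop("'replicate_table' must be numeric with >= 2 replicate columns",
         call. = FALSE)
  j <- rowSums(!is.na(m))
  usable <- j >= 2
  if (sum(usable) < 10)
    stop("need >= 10 genes with at least two replicates", call. = FALSE)
  if (any(!usable))
    message(sprintf("%d gene(s) with fewer than 2 replicates skipped",
                    sum(!usable)))
  mu <- m[usable, , drop = FALSE]
  dev2 <- (mu - rowMeans(mu, na.rm = TRUE))^2
  est <- sum(dev2, na.rm = TRUE) / sum(j[usable] - 1)
  attr(est, "n_genes_used") <- sum(usable)
  est
}

#' Fit the gold-standard mRNA regression
#'
#' OLS of gold-standard (e.g. NanoString) log10 values on survey (RNA-Seq)
#' log10 values after removing the `n_outliers_removed` points with the
#' largest absolute residuals from an initial fit.  The residual variance
#' of this regression estimates the systematic mRNA measurement-error
#' variance.
#'
#' @param gold_pairs data.frame with `reference_log10` and `survey_log10`.
#' @param n_outliers_removed number of largest-residual points to drop
#'   (default 2).
#' @return list with `b_R` (slope), `sigma_R2` (residual variance,
#'   denominator n - 2), `intercept` and `n_used`.
#' @export
fit_gold_rna <- function(gold_pairs, n_outliers_removed = 2) {
  x <- gold_pairs$survey_log10
  y <- gold_pairs$reference_log10
  check_finite_vector(x, "survey_log10", 10L)
  check_finite_vector(y, "reference_log10", 10L)
  check_number(n_outliers_removed, "n_outliers_removed", min = 0)
  if (n_outliers_removed >= length(x))
    stop("cannot remove as many outliers as there are pairs", call. = FALSE)
  if (n_outliers_removed > 0) {
    fit0 <- ols_fit(x, y)
    keep <- order(abs(fit0$residuals),
                  decreasing = TRUE)[-seq_len(n_outliers_removed)]
    x <- x[sort(keep)]; y <- y[sort(keep)]
  }
  fit <- ols_fit(x, y)
  list(b_R = fit$slope, sigma_R2 = fit$rss / (fit$n - 2),
       intercept = fit$intercept, n_used = fit$n)
}

pooled_points <- function(expression) {
  mr <- c(expression$mrna_1, expression$mrna_2)
  mp <- c(expression$protein_1, expression$protein_2)
  ok <- is.finite(mr) & is.finite(mp)
  list(mr = mr[ok], mp = mp[ok], n = sum(ok))
}

#' Measured-protein-error variance decomposition
#'
#' Decomposes the residual variance \eqn{\sigma^2_{all}} of the pooled
#' regression of measured protein on measured mRNA (both replicates
#' stacked) into three independent components: systematic mRNA error
#' \eqn{(b_{all}/b_R)^2 \sigma^2_R} (from the gold-standard mRNA
#' comparison), stochastic protein error \eqn{\sigma^2_P} (from the
#' protein replicates), and the remainder \eqn{\sigma^2_{PDT}}, the
#' genuine between-gene variance in protein degradation and translation.
#' From these, the fraction of variance in true protein levels explained
#' by true mRNA levels is
#' \deqn{(\sigma^2_{MP} - \sigma^2_P - \sigma^2_{PDT}) /
#'       (\sigma^2_{MP} - \sigma^2_P).}
#'
#' Systematic protein error cannot be separated with these inputs and is
#' implicitly part of \eqn{\sigma^2_{PDT}}; the mRNA-explained fraction is
#' therefore a lower bound.
#'
#' @param expression an [expression_table()]; for this strategy the
#'   protein columns should be on the calibrated (corrected) scale, or a
#'   `correction` model should be supplied.
#' @param gold_rna data.frame of gold vs survey mRNA pairs
#'   (`reference_log10`, `survey_log10`).
#' @param correction optional [segmented_model()] applied to the protein
#'   replicates before decomposing.
#' @param n_outliers_removed outliers dropped in [fit_gold_rna()].
#' @return object of class `"variance_components"`.
#' @export
decompose_measured_error <- function(expression, gold_rna,
                                     correction = NULL,
                                     n_outliers_removed = 2) {
  if (!is.null(correction)) {
    expression$protein_1 <- apply_correction(correction,
                                             expression$protein_1)
    expression$protein_2 <- apply_correction(correction,
                                             expression$protein_2)
  }
  pts <- pooled_points(expression)
  if (pts$n < 20)
    stop("too few pooled replicate points for the decomposition",
         call. = FALSE)
  fit_all <- ols_fit(pts$mr, pts$mp)
  sigma_all2 <- fit_all$rss / (pts$n - 2)
  sigma_MP2 <- var(pts$mp)
  sigma_P2 <- as.numeric(stochastic_error_from_replicates(
    expression[c("protein_1", "protein_2")]))
  sigma_R2_stochastic <- as.numeric(stochastic_error_from_replicates(
    expression[c("mrna_1", "mrna_2")]))
  gold <- fit_gold_rna(gold_rna, n_outliers_removed)
  rna_component <- (fit_all$slope / gold$b_R)^2 * gold$sigma_R2
  sigma_PDT2 <- sigma_all2 - rna_component - sigma_P2
  if (sigma_PDT2 < 0)
    stop(sprintf(paste0("inconsistent inputs: estimated var(PDT) is ",
                        "negative (%.4g); measurement-error estimates ",
                        "exceed the residual variance"), sigma_PDT2),
         call. = FALSE)
  pct_mrna_of_true <- 100 * (sigma_MP2 - sigma_P2 - sigma_PDT2) /
    (sigma_MP2 - sigma_P2)
  structure(list(sigma_all2 = sigma_all2, b_all = fit_all$slope,
                 sigma_R2 = gold$sigma_R2, b_R = gold$b_R,
                 sigma_P2 = sigma_P2,
                 sigma_PDT2 = sigma_PDT2, sigma_MP2 = sigma_MP2,
                 sigma_R2_stochastic = sigma_R2_stochastic,
                 rna_component = rna_component,
                 pct_rna_error = 100 * rna_component / sigma_all2,
                 pct_protein_error = 100 * sigma_P2 / sigma_all2,
                 pct_pdt = 100 * sigma_PDT2 / sigma_all2,
                 pct_mrna_of_true = pct_mrna_of_true,
                 n_pooled = pts$n),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance decomposition of the protein-on-mRNA residuals (log10^2)\n")
  cat(sprintf("  residual variance sigma_all^2 = %.4f (%d pooled points)\n",
              x$sigma_all2, x$n_pooled))
  cat(sprintf("    systematic mRNA error : %.4f (%.1f%%)\n",
              x$rna_component, x$pct_rna_error))
  cat(sprintf("    stochastic protein err: %.4f (%.1f%%)\n",
              x$sigma_P2, x$pct_protein_error))
  cat(sprintf("    degradation+translation: %.4f (%.1f%%)\n",
              x$sigma_PDT2, x$pct_pdt))
  cat(sprintf("  true mRNA explains >= %.1f%% of true protein variance\n",
              x$pct_mrna_of_true))
  invisible(x)
}

new_four_step_shares <- function(strategy, var_TP, pct_mRNA, pct_TXN,
                                 pct_RD, pct_PT, pct_PD, details = list()) {
  shares <- c(pct_TXN = pct_TXN, pct_RD = pct_RD, pct_PT = pct_PT,
              pct_PD = pct_PD)
  neg <- shares[shares < 0]
  if (length(neg))
    stop(sprintf("negative percent contribution for %s (%.2f%%): inputs are inconsistent",
                 sub("pct_", "", names(neg)[1]), neg[[1]]), call. = FALSE)
  structure(list(strategy = strategy, var_TP = var_TP, pct_mRNA = pct_mRNA,
                 pct_TXN = pct_TXN, pct_RD = pct_RD, pct_PT = pct_PT,
                 pct_PD = pct_PD, details = details),
            class = "four_step_shares")
}

#' @export
print.four_step_shares <- function(x, ...) {
  cat(sprintf("Percent contribution to variance in protein levels (%s)\n",
              x$strategy))
  cat(sprintf("  var(true protein), log10^2: %.2f\n", x$var_TP))
  cat(sprintf("  mRNA %d%% | transcription %d%% | RNA degradation %d%% | translation %d%% | protein degradation %d%%\n",
              round(x$pct_mRNA), round(x$pct_TXN), round(x$pct_RD),
              round(x$pct_PT), round(x$pct_PD)))
  invisible(x)
}

#' Four-step shares from the measured-protein-error decomposition
#'
#' Converts a [decompose_measured_error()] result into percent
#' contributions of the four gene-expression steps, given externally
#' measured variances of mRNA degradation and protein degradation:
#' \deqn{var(TP) = \sigma^2_{MP} - \sigma^2_P, \quad
#'       var(TR) = var(TP) - \sigma^2_{PDT}}
#' \deqn{TXN = (var(TR) - var(RD))/var(TP), \quad
#'       PT = (var(TP) - var(TR) - var(PD))/var(TP).}
#'
#' @param components a `"variance_components"` object.
#' @param var_RD variance contributed by mRNA degradation (log10^2).
#' @param var_PD variance contributed by protein degradation (log10^2).
#' @return object of class `"four_step_shares"`.
#' @export
four_step_from_measured_error <- function(components, var_RD = 0.062,
                                          var_PD = 0.048) {
  stopifnot(inherits(components, "variance_components"))
  check_number(var_RD, "var_RD", min = 0)
  check_number(var_PD, "var_PD", min = 0)
  var_TP <- components$sigma_MP2 - components$sigma_P2
  var_TR <- var_TP - components$sigma_PDT2
  new_four_step_shares(
    strategy = "measured protein error",
    var_TP = var_TP,
    pct_mRNA = 100 * var_TR / var_TP,
    pct_TXN = 100 * (var_TR - var_RD) / var_TP,
    pct_RD = 100 * var_RD / var_TP,
    pct_PT = 100 * (var_TP - var_TR - var_PD) / var_TP,
    pct_PD = 100 * var_PD / var_TP,
    details = list(var_TR = var_TR, var_RD = var_RD, var_PD = var_PD,
                   components = components))
}

#' Constants for the measured-translation strategy
#'
#' Bundles the externally supplied quantities the measured-translation
#' decomposition needs: the total measured-protein variance of the source
#' survey, the source study's inferred percent contributions of
#' translation, protein degradation and RNA degradation, the per-gene
#' variance of the source's inferred translation rates, and the directly
#' measured (ribosome-profiling) translation-rate variance.
#'
#' `var_dPT_inferred` optionally overrides the product
#' `sigma_MP2 * pct_PT_inferred / 100` (e.g. to use a source study's own
#' rounded figure).
#'
#' @param sigma_MP2 total measured-protein log10 variance of the source
#'   survey (default 0.97).
#' @param pct_PT_inferred,pct_PD_inferred,pct_RD_inferred source-study
#'   percent contributions (defaults 55, 4.9, 6.4; the protein-degradation
#'   share is often quoted as "5%" but the arithmetic behind the published
#'   0.0475 uses 4.9).
#' @param var_PT_inferred_pergene per-gene variance of the inferred
#'   translation rates (default 0.29).
#' @param var_PT_measured directly measured translation-rate variance
#'   (default 0.03533, see [adjust_variance_to_superset()]).
#' @param var_dPT_inferred optional override of the inferred translation
#'   contribution, log10^2.
#' @return object of class `"translation_inputs"`.
#' @export
translation_inputs <- function(sigma_MP2 = 0.97, pct_PT_inferred = 55,
                               pct_PD_inferred = 4.9, pct_RD_inferred = 6.4,
                               var_PT_inferred_pergene = 0.29,
                               var_PT_measured = 0.03533,
                               var_dPT_inferred = NULL) {
  check_number(sigma_MP2, "sigma_MP2", min = 0)
  for (nm in c("pct_PT_inferred", "pct_PD_inferred", "pct_RD_inferred")) {
    v <- check_number(get(nm), nm, min = 0)
    if (v > 100) stop(sprintf("'%s' must be a percentage in [0, 100]", nm),
                      call. = FALSE)
  }
  check_number(var_PT_inferred_pergene, "var_PT_inferred_pergene", min = 0)
  check_number(var_PT_measured, "var_PT_measured", min = 0)
  check_number(var_dPT_inferred, "var_dPT_inferred", min = 0,
               allow_null = TRUE)
  structure(list(sigma_MP2 = sigma_MP2, pct_PT_inferred = pct_PT_inferred,
                 pct_PD_inferred = pct_PD_inferred,
                 pct_RD_inferred = pct_RD_inferred,
                 var_PT_inferred_pergene = var_PT_inferred_pergene,
                 var_PT_measured = var_PT_measured,
                 var_dPT_inferred = var_dPT_inferred),
            class = "translation_inputs")
}

#' Desk arithmetic of the measured-translation constants
#'
#' From the supplied constants alone, computes the protein-degradation
#' variance `var_cPD = sigma_MP2 * pct_PD/100`, the squared translation
#' scaling `d_squared = var_dPT_inferred / var_PT_inferred_pergene` and the
#' replacement translation contribution
#' `var_dPT = d_squared * var_PT_measured`.
#'
#' @param inputs a [translation_inputs()] object.
#' @return list with `var_cPD`, `d_squared`, `var_dPT`,
#'   `var_dPT_inferred` and `var_gRD`.
#' @export
translation_strategy_constants <- function(inputs) {
  stopifnot(inherits(inputs, "translation_inputs"))
  var_dPT_inferred <- if (is.null(inputs$var_dPT_inferred))
    inputs$sigma_MP2 * inputs$pct_PT_inferred / 100
  else inputs$var_dPT_inferred
  if (inputs$var_PT_inferred_pergene <= 0)
    stop("'var_PT_inferred_pergene' must be positive", call. = FALSE)
  d_squared <- var_dPT_inferred / inputs$var_PT_inferred_pergene
  list(var_cPD = inputs$sigma_MP2 * inputs$pct_PD_inferred / 100,
       d_squared = d_squared,
       var_dPT = d_squared * inputs$var_PT_measured,
       var_dPT_inferred = var_dPT_inferred,
       var_gRD = inputs$sigma_MP2 * inputs$pct_RD_inferred / 100)
}

#' Measured-translation variance decomposition
#'
#' The second, independent strategy: instead of relying on a rescaling of
#' the survey or on replicate-based protein error, it takes translation
#' and protein-degradation variances from direct measurements and infers
#' the (total) protein measurement error as the unexplained remainder of
#' the residual variance:
#' \deqn{\sigma^2_P = \sigma^2_{all} - (b_{all}/b_R)^2 \sigma^2_R
#'       - var(cPD) - var(dPT)}
#' where \eqn{var(dPT) = d^2 var(PT_{measured})} and
#' \eqn{d^2} converts the translation-rate axis to protein log10 units
#' (see [translation_strategy_constants()]).  Then
#' \eqn{var(TP) = \sigma^2_{MP} - \sigma^2_P} and the four steps'
#' contributions follow.
#'
#' This strategy operates on the uncorrected survey abundances: it is
#' independent of the two-part recalibration.
#'
#' @param expression an [expression_table()] with uncorrected survey
#'   protein values.
#' @param gold_rna gold vs survey mRNA pairs, as in
#'   [decompose_measured_error()].
#' @param inputs a [translation_inputs()] object.
#' @param n_outliers_removed outliers dropped in [fit_gold_rna()].
#' @param square_slope logical; use \eqn{(b_{all}/b_R)^2} (dimensionally
#'   consistent, the default) rather than the unsquared ratio when
#'   propagating the systematic mRNA error.
#' @return object of class `"four_step_shares"`, with estimator internals
#'   in `$details`.
#' @export
decompose_measured_translation <- function(expression, gold_rna,
                                           inputs = translation_inputs(),
                                           n_outliers_removed = 2,
                                           square_slope = TRUE) {
  stopifnot(inherits(inputs, "translation_inputs"))
  pts <- pooled_points(expression)
  if (pts$n < 20)
    stop("too few pooled replicate points for the decomposition",
         call. = FALSE)
  fit_all <- ols_fit(pts$mr, pts$mp)
  sigma_all2 <- fit_all$rss / (pts$n - 2)
  sigma_MP2 <- if (is.null(inputs$sigma_MP2)) var(pts$mp) else
    inputs$sigma_MP2
  gold <- fit_gold_rna(gold_rna, n_outliers_removed)
  bhat <- fit_all$slope / gold$b_R
  cons <- translation_strategy_constants(inputs)
  rna_component <- (if (square_slope) bhat^2 else bhat) * gold$sigma_R2
  sigma_P2 <- sigma_all2 - rna_component - cons$var_cPD - cons$var_dPT
  if (sigma_P2 < 0)
    stop(sprintf(paste0("inconsistent inputs: inferred protein-error ",
                        "variance is negative (%.4g)"), sigma_P2),
         call. = FALSE)
  var_TP <- sigma_MP2 - sigma_P2
  if (var_TP <= 0)
    stop("inconsistent inputs: var(TP) is not positive", call. = FALSE)
  pct_PD <- 100 * cons$var_cPD / var_TP
  pct_PT <- 100 * cons$var_dPT / var_TP
  pct_mRNA <- 100 - pct_PD - pct_PT
  pct_RD <- 100 * cons$var_gRD / var_TP
  new_four_step_shares(
    strategy = "measured translation",
    var_TP = var_TP,
    pct_mRNA = pct_mRNA, pct_TXN = pct_mRNA - pct_RD, pct_RD = pct_RD,
    pct_PT = pct_PT, pct_PD = pct_PD,
    details = c(cons, list(sigma_all2 = sigma_all2, b_all = fit_all$slope,
                           b_R = gold$b_R, sigma_R2 = gold$sigma_R2,
                           rna_component = rna_component,
                           sigma_P2 = sigma_P2, sigma_MP2 = sigma_MP2,
                           square_slope = square_slope)))
}

#' Upper bound on true translation variance in an inferred-rate axis
#'
#' Cross-check linking the two strategies: the ratio of the true
#' translation contribution estimated by the measured-protein-error
#' strategy to the translation contribution claimed by the source survey,
#' \deqn{(var(TP) \cdot pct_{PT}) / (\sigma^2_{MP,source} \cdot
#'       pct_{PT,source}),}
#' bounds the fraction of the inferred translation-rate variance that can
#' be genuine signal.
#'
#' @param shares_measured_error a `"four_step_shares"` object from the
#'   measured-protein-error strategy.
#' @param sigma_MP2_source source-survey protein variance (default 0.97).
#' @param pct_PT_source source-survey translation percentage (default 55).
#' @return the ratio (dimensionless).
#' @export
inferred_translation_variance_bound <- function(shares_measured_error,
                                                sigma_MP2_source = 0.97,
                                                pct_PT_source = 55) {
  stopifnot(inherits(shares_measured_error, "four_step_shares"))
  check_number(sigma_MP2_source, "sigma_MP2_source", min = 0)
  check_number(pct_PT_source, "pct_PT_source", min = 0)
  (shares_measured_error$var_TP * shares_measured_error$pct_PT) /
    (sigma_MP2_source * pct_PT_source)
}
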