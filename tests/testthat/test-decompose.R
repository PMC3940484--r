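# Variance decomposition: the replicate-error estimator, the
# gold-standard mRNA regression, both strategies and their identities.

fake_components <- function(sigma_MP2, sigma_P2, sigma_PDT2, sigma_all2,
                            b_all = 1, b_R = 1, sigma_R2 = 0) {
  structure(list(sigma_all2 = sigma_all2, b_all = b_all,
                 sigma_R2 = sigma_R2, b_R = b_R, sigma_P2 = sigma_P2,
                 sigma_PDT2 = sigma_PDT2, sigma_MP2 = sigma_MP2,
                 sigma_R2_stochastic = 0,
                 rna_component = sigma_all2 - sigma_P2 - sigma_PDT2,
                 pct_mrna_of_true = NA_real_, n_pooled = 0),
            class = "variance_components")
}

test_that("the pooled replicate estimator recovers injected noise and is
           zero for identical replicates", {
  m <- matrix(rnorm(40), ncol = 2)
  expect_equal(stochastic_error_from_replicates(cbind(m[, 1], m[, 1])), 0,
               ignore_attr = TRUE)
  set.seed(12)
  mu <- rnorm(5000, 5, 1)
  reps <- cbind(mu + rnorm(5000, 0, 0.2), mu + rnorm(5000, 0, 0.2))
  est <- stochastic_error_from_replicates(reps)
  expect_equal(as.numeric(est), 0.04, tolerance = 0.1)
  # genes with a single replicate are skipped and counted
  reps[1:7, 2] <- NA
  expect_message(est2 <- stochastic_error_from_replicates(reps), "7")
  expect_equal(attr(est2, "n_genes_used"), 4993)
  expect_error(stochastic_error_from_replicates(reps[, 1, drop = FALSE]),
               "replicate")
})

test_that("stochastic error estimates increase with injected noise", {
  set.seed(3)
  mu <- rnorm(2000, 5, 1)
  ests <- vapply(c(0.05, 0.1, 0.2, 0.4), function(s)
    as.numeric(stochastic_error_from_replicates(
      cbind(mu + rnorm(2000, 0, s), mu + rnorm(2000, 0, s)))), numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("gold-standard mRNA regression recovers slope and residual
           variance, with outlier trimming", {
  x <- seq(0, 3, length.out = 30)
  exact <- fit_gold_rna(data.frame(survey_log10 = x,
                                   reference_log10 = 1.2 * x + 0.1),
                        n_outliers_removed = 0)
  expect_equal(exact$b_R, 1.2)
  expect_equal(exact$sigma_R2, 0, tolerance = 1e-20)

  # known residual sd 0.2 at n = 77: the average estimate over seeds is
  # within 15% of 0.04
  ests <- vapply(1:20, function(s) {
    set.seed(s)
    xs <- runif(77, 0, 3)
    fit_gold_rna(data.frame(survey_log10 = xs,
                            reference_log10 = xs + rnorm(77, 0, 0.2)),
                 n_outliers_removed = 0)$sigma_R2
  }, numeric(1))
  expect_equal(mean(ests), 0.04, tolerance = 0.15)

  # trimming the two largest residuals shrinks the estimate
  set.seed(5)
  xs <- runif(77, 0, 3)
  gp <- data.frame(survey_log10 = xs,
                   reference_log10 = xs + rnorm(77, 0, 0.2))
  expect_lt(fit_gold_rna(gp, 2)$sigma_R2, fit_gold_rna(gp, 0)$sigma_R2)
  expect_error(fit_gold_rna(gp, 77), "outliers")
})

test_that("error-free synthetic data decomposes into pure biology", {
  p <- simulation_params(n_genes = 3000, sd_eR = 0, sd_eR_rep = 0,
                         sd_eP_rep = 0, sd_ref = 0, sd_ref_rna = 0,
                         n_gold_protein = 50, n_gold_rna = 50,
                         n_rate_inferred = 100, n_rate_measured = 100,
                         n_rate_overlap = 100, compression = NULL,
                         seed = 21)
  b <- generate_expression_dataset(p)
  vc <- decompose_measured_error(b$expression, b$rna_gold,
                                 n_outliers_removed = 0)
  expect_equal(vc$sigma_P2, 0, ignore_attr = TRUE)
  expect_equal(vc$sigma_R2, 0, tolerance = 1e-12)
  # with no measurement error the remainder is exactly the residual
  # variance of an independent lm() fit, and the mRNA-explained share is
  # that fit's R^2 (equivalently the squared correlation with true mRNA)
  mr <- c(b$expression$mrna_1, b$expression$mrna_2)
  mp <- c(b$expression$protein_1, b$expression$protein_2)
  fit <- lm(mp ~ mr)
  expect_equal(vc$sigma_PDT2, sum(resid(fit)^2) / (length(mr) - 2),
               tolerance = 1e-12)
  expect_equal(vc$pct_mrna_of_true, 100 * summary(fit)$r.squared,
               tolerance = 2e-3)
  expect_equal(vc$pct_mrna_of_true, truth_shares(b)$mRNA, tolerance = 2e-3)
})

test_that("the decomposition identity holds to machine precision and
           components are reproducible", {
  b <- small_bundle()
  vc <- decompose_measured_error(b$expression, b$rna_gold)
  expect_equal(vc$sigma_all2,
               (vc$b_all / vc$b_R)^2 * vc$sigma_R2 + vc$sigma_P2 +
                 vc$sigma_PDT2, tolerance = 1e-12)
  vc2 <- decompose_measured_error(b$expression, b$rna_gold)
  expect_identical(vc[setdiff(names(vc), "n_pooled")],
                   vc2[setdiff(names(vc2), "n_pooled")])
})

test_that("negative remainder variance raises an inconsistency error", {
  # gold pairs with huge residual variance force var(PDT) < 0
  set.seed(9)
  b <- small_bundle()
  noisy <- b$rna_gold
  noisy$reference_log10 <- noisy$reference_log10 + rnorm(nrow(noisy), 0, 3)
  expect_error(decompose_measured_error(b$expression, noisy),
               "inconsistent|negative")
})

test_that("four-step shares obey their algebraic identities", {
  vc <- fake_components(sigma_MP2 = 0.40, sigma_P2 = 0.02,
                        sigma_PDT2 = 0.15, sigma_all2 = 0.22)
  # no degradation: transcription is all of mRNA, translation the rest
  s0 <- four_step_from_measured_error(vc, var_RD = 0, var_PD = 0)
  expect_equal(s0$pct_TXN, s0$pct_mRNA)
  expect_equal(s0$pct_PT, 100 - s0$pct_mRNA)
  # random admissible inputs: shares sum exactly before rounding
  set.seed(77)
  for (i in 1:25) {
    mp2 <- runif(1, 0.3, 1.2)
    p2 <- runif(1, 0, 0.1 * mp2)
    pdt <- runif(1, 0.05, 0.4) * mp2
    all2 <- pdt + p2 + runif(1, 0, 0.1)
    var_tp <- mp2 - p2
    var_tr <- var_tp - pdt
    vrd <- runif(1, 0, 0.8 * var_tr)
    vpd <- runif(1, 0, 0.8 * (var_tp - var_tr))
    s <- four_step_from_measured_error(
      fake_components(mp2, p2, pdt, all2), var_RD = vrd, var_PD = vpd)
    expect_equal(s$pct_TXN + s$pct_RD + s$pct_PT + s$pct_PD, 100,
                 tolerance = 1e-10)
    expect_equal(s$pct_TXN + s$pct_RD, s$pct_mRNA, tolerance = 1e-10)
    expect_equal(s$pct_mRNA + s$pct_PT + s$pct_PD, 100, tolerance = 1e-10)
  }
  # impossible degradation variances are refused with the term named
  expect_error(four_step_from_measured_error(vc, var_RD = 1, var_PD = 0),
               "TXN")
})

test_that("measured-translation strategy collapses to the source claim
           when measured equals inferred variance", {
  ti <- translation_inputs(sigma_MP2 = 0.97, pct_PT_inferred = 55,
                           var_PT_inferred_pergene = 0.29,
                           var_PT_measured = 0.29)
  cons <- translation_strategy_constants(ti)
  expect_equal(cons$var_dPT, 0.97 * 0.55)
  expect_equal(cons$var_cPD, 0.97 * 0.049)
})

test_that("both strategies recover generator-truth shares on synthetic
           bundles", {
  p <- simulation_params(n_genes = 5000, n_gold_rna = 800,
                         compression = NULL, seed = 123)
  b <- generate_expression_dataset(p)
  truth <- truth_shares(b)

  vc <- decompose_measured_error(b$expression, b$rna_gold,
                                 n_outliers_removed = 0)
  s1 <- four_step_from_measured_error(vc, var_RD = 0,
                                      var_PD = var(b$truth$PD))
  expect_equal(s1$pct_mRNA, truth$mRNA, tolerance = 5 / truth$mRNA)
  expect_equal(s1$pct_PT, truth$PT, tolerance = 5 / truth$PT)
  expect_equal(s1$var_TP, truth$var_TP, tolerance = 0.1)

  s2 <- decompose_measured_translation(b$expression, b$rna_gold,
                                       consistent_translation_inputs(b),
                                       n_outliers_removed = 0)
  expect_equal(s2$pct_mRNA, truth$mRNA, tolerance = 5 / truth$mRNA)
  expect_equal(s2$pct_PT, truth$PT, tolerance = 5 / truth$PT)
  expect_equal(s2$pct_PD, truth$PD, tolerance = 5 / truth$PD)
})

test_that("the translation-variance cross-check behaves like a bound and
           reproduces the hand-computed ratio", {
  s <- four_step_from_measured_error(
    fake_components(sigma_MP2 = 0.36, sigma_P2 = 0.02, sigma_PDT2 = 0.15,
                    sigma_all2 = 0.22), var_RD = 0.05, var_PD = 0.048)
  same <- inferred_translation_variance_bound(
    s, sigma_MP2_source = s$var_TP, pct_PT_source = s$pct_PT)
  expect_equal(same, 1)
  # synthetic bundle: the bound exceeds the realised measured-vs-inferred
  # r-squared (attenuation consistency)
  b <- default_bundle()
  cmp <- intersect_and_compare(b$translation$measured,
                               b$translation$inferred)
  vc <- decompose_measured_error(b$expression, b$rna_gold,
                                 correction = fit_segmented(b$calibration))
  sh <- four_step_from_measured_error(vc)
  pooled_var <- var(c(b$expression$protein_1, b$expression$protein_2))
  bound <- inferred_translation_variance_bound(
    sh, sigma_MP2_source = pooled_var, pct_PT_source = 55)
  expect_gte(bound, cmp$r_squared)
})
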