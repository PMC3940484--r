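# Shared fixtures, built in code and memoised so expensive bundles are
# generated once per test run.

bundle_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(bundle_cache[[key]])) bundle_cache[[key]] <- builder()
  bundle_cache[[key]]
}

# Paper-scale default bundle (5,028 genes, survey compression active).
default_bundle <- function(seed = 1) {
  cached(sprintf("default-%d", seed), function()
    suppressMessages(generate_expression_dataset(
      simulation_params(seed = seed))))
}

# Small uncompressed bundle for fast unit tests.
small_bundle <- function(seed = 5, n_genes = 600) {
  cached(sprintf("small-%d-%d", seed, n_genes), function()
    suppressMessages(generate_expression_dataset(simulation_params(
      n_genes = n_genes, n_gold_protein = 50, n_gold_rna = 50,
      n_rate_inferred = 400, n_rate_measured = 350, n_rate_overlap = 300,
      compression = NULL, seed = seed))))
}

# The two-part survey distortion used throughout: change point at 10^6
# with segment slopes 0.56 / 1.06 and intercepts 2.64 / -0.41.
reference_two_part <- function() segmented_model(6, 0.56, 2.64, 1.06, -0.41)

# Ground-truth percent contributions realised in a bundle's truth table:
# the mRNA share is the sample variance of true protein explained by true
# mRNA (squared correlation, which includes the finite-sample covariance
# between TR and the biological deviations); PT and PD are plain variance
# ratios.
truth_shares <- function(bundle) {
  tr <- bundle$truth
  v_tp <- var(tr$TP)
  list(mRNA = 100 * cor(tr$TP, tr$TR)^2,
       PT = 100 * var(tr$PT) / v_tp,
       PD = 100 * var(tr$PD) / v_tp,
       var_TP = v_tp)
}

# Measured-translation inputs that are internally consistent with the
# generator: the inferred-axis variance converted to protein log10 units
# with the true scaling d, plus the true protein-degradation share.
consistent_translation_inputs <- function(bundle) {
  pts_mp <- c(bundle$expression$protein_1, bundle$expression$protein_2)
  sigma_MP2 <- var(pts_mp)
  v_inf <- var(log10(bundle$translation$inferred$rate))
  translation_inputs(
    sigma_MP2 = sigma_MP2,
    pct_PD_inferred = 100 * var(bundle$truth$PD) / sigma_MP2,
    pct_RD_inferred = 0,
    var_PT_inferred_pergene = v_inf,
    var_PT_measured = var(log10(bundle$translation$measured$rate)),
    var_dPT_inferred = v_inf / bundle$params$d^2)
}
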