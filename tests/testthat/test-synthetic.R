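# Synthetic-data generator: determinism, degenerate limits, moment
# convergence, and the closed loop between survey compression and
# calibration.

zero_noise_params <- function(...) {
  simulation_params(
    n_genes = 50, b = 1, c = 0, b_R = 1, c_R = 0, c_P = 0,
    sd_MR = 0, sd_eR = 0, sd_eR_rep = 0, sd_PD = 0, sd_PT = 0, sd_f = 0,
    sd_eP_rep = 0, sd_ref = 0, sd_ref_rna = 0,
    sd_rate_measured = 0, sd_rate_inferred = 0,
    n_gold_protein = 10, n_gold_rna = 10,
    n_rate_inferred = 20, n_rate_measured = 20, n_rate_overlap = 20,
    compression = NULL, seed = 1, ...)
}

test_that("the zero-noise identity chain collapses measurements onto
           true values", {
  b <- generate_expression_dataset(zero_noise_params())
  ex <- b$expression
  expect_equal(ex$protein_1, ex$mrna_1)
  expect_equal(ex$protein_2, ex$mrna_2)
  expect_equal(ex$mrna_1, b$truth$TR)
  expect_equal(ex$protein_1, b$truth$TP)
  expect_equal(b$calibration$reference_log10, b$calibration$survey_log10)
})

test_that("with error sds zero but biology on, measured equals true for
           every quantity", {
  p <- simulation_params(n_genes = 200, sd_eR = 0, sd_eR_rep = 0,
                         sd_eP_rep = 0, sd_ref = 0, sd_ref_rna = 0,
                         n_gold_protein = 20, n_gold_rna = 20,
                         n_rate_inferred = 50, n_rate_measured = 50,
                         n_rate_overlap = 50, compression = NULL, seed = 2)
  b <- generate_expression_dataset(p)
  expect_equal(b$expression$mrna_1, b$expression$mrna_2)
  expect_equal(b$truth$TR, p$b_R * b$expression$mrna_1 + p$c_R)
  expect_equal(b$expression$protein_1, b$truth$TP + p$c_P)
  idx <- match(b$calibration$gene_id, b$truth$gene_id)
  expect_equal(b$calibration$reference_log10, b$truth$TP[idx] + p$c_P)
})

test_that("identical parameters and seed give byte-identical bundles", {
  p <- simulation_params(n_genes = 300, n_gold_protein = 30,
                         n_gold_rna = 30, n_rate_inferred = 100,
                         n_rate_measured = 90, n_rate_overlap = 80,
                         seed = 99)
  expect_identical(generate_expression_dataset(p),
                   generate_expression_dataset(p))
})

test_that("sample moments converge to the generating parameters", {
  p <- simulation_params(n_genes = 5000, seed = 1)
  b <- generate_expression_dataset(p)
  expect_equal(var(b$truth$PD), p$sd_PD^2, tolerance = 0.1)
  expect_equal(var(b$truth$PT), p$sd_PT^2, tolerance = 0.1)
  expect_equal(var(b$truth$TR - p$b_R * (p$mu_MR) - p$c_R),
               p$sd_MR^2 + p$sd_eR^2, tolerance = 0.1)
  expect_equal(mean(b$truth$TP), p$b * (p$b_R * p$mu_MR + p$c_R) + p$c,
               tolerance = 0.01)
  # replicate differences estimate twice the stochastic error variance
  expect_equal(var(b$expression$mrna_1 - b$expression$mrna_2) / 2,
               p$sd_eR_rep^2, tolerance = 0.1)
})

test_that("all bundle tables share the gene-identifier namespace and the
           truth table is complete", {
  b <- small_bundle()
  ids <- b$truth$gene_id
  expect_false(anyNA(b$truth))
  expect_true(all(b$expression$gene_id == ids))
  expect_true(all(b$calibration$gene_id %in% ids))
  expect_true(all(b$rna_gold$gene_id %in% ids))
  expect_true(all(b$translation$measured$gene_id %in% ids))
  expect_true(all(b$translation$inferred$gene_id %in% ids))
  expect_equal(length(intersect(b$translation$measured$gene_id,
                                b$translation$inferred$gene_id)),
               b$params$n_rate_overlap)
})

test_that("survey compression closes the loop: calibrating the gold
           pairs recovers the compression model", {
  p <- simulation_params(n_genes = 2000, sd_eP_rep = 0, sd_ref = 0,
                         n_gold_protein = 80, gold_protein_bias = 1,
                         n_rate_inferred = 500, n_rate_measured = 450,
                         n_rate_overlap = 400, seed = 4)
  b <- generate_expression_dataset(p)
  # noise-free gold pairs sit exactly on the compression map
  expect_equal(apply_correction(p$compression, b$calibration$survey_log10),
               b$calibration$reference_log10, tolerance = 1e-10)
  m <- fit_segmented(b$calibration)
  expect_equal(m$lower_slope, 0.56, tolerance = 1e-6)
  expect_equal(m$upper_slope, 1.06, tolerance = 1e-6)
})

test_that("parameter validation names the offending field", {
  expect_error(simulation_params(sd_PD = -1), "sd_PD")
  expect_error(simulation_params(b = NaN), "'b'")
  expect_error(simulation_params(n_gold_rna = 10000), "n_gold_rna")
  expect_error(simulation_params(n_rate_overlap = 4000), "n_rate_overlap")
})

test_that("calibration-set generation enforces its preconditions and the
           identity model yields y = x", {
  expect_error(generate_calibration_set(reference_two_part(), n = 3), "n")
  id <- segmented_model(5, 1, 0, 1, 0)
  p <- generate_calibration_set(id, n = 30, noise_sd = 0, seed = 8)
  expect_equal(p$reference_log10, p$survey_log10)
})

test_that("trimodal generator honours its fractions and mode centres", {
  expect_error(trimodal_params(frac_NE = 0.8, frac_LE = 0.4), "sum")
  all_ne <- generate_trimodal_mrna(trimodal_params(n_genes = 100,
                                                   frac_NE = 1,
                                                   frac_LE = 0, seed = 1))
  expect_true(all(is.na(all_ne$abundance)))

  # default mode locations: LE centred at 0.1 and HE at 10 molecules/cell
  le <- generate_trimodal_mrna(trimodal_params(n_genes = 20000,
                                               frac_NE = 0, frac_LE = 1,
                                               seed = 2))
  expect_equal(mean(log10(le$abundance)), -1, tolerance = 0.02)
  he <- generate_trimodal_mrna(trimodal_params(n_genes = 20000,
                                               frac_NE = 0, frac_LE = 0,
                                               seed = 3))
  expect_equal(mean(log10(he$abundance)), 1, tolerance = 0.02)

  # determinism
  tp <- trimodal_params(n_genes = 500, seed = 7)
  expect_identical(generate_trimodal_mrna(tp), generate_trimodal_mrna(tp))
})
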