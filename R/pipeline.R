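# Orchestration: a run configuration and the full analysis chain
# (calibration -> correlation -> variance decomposition -> translation
# comparison -> census), with a manifest recording seeds and versions.

#' Build a pipeline run configuration
#'
#' Collects input table paths, strategy constants and run options for
#' [run_full_pipeline()].  The `translation_*` and `census` inputs are
#' optional; stages without inputs are skipped.
#'
#' @param calibration_pairs path to the gold-standard protein pairs TSV
#'   (see [read_calibration_pairs()]).
#' @param expression path to the survey expression TSV
#'   (see [read_expression_table()]).
#' @param rna_gold path to the gold vs survey mRNA TSV.
#' @param translation_measured,translation_inferred optional paths to
#'   translation-rate TSVs.
#' @param census optional path to a population mRNA abundance TSV.
#' @param strategy decomposition strategies to run: subset of
#'   `"measured-error"`, `"measured-translation"`.
#' @param n_boot bootstrap replicates for the calibration LRT.
#' @param seed integer seed recorded in the manifest and used for the
#'   bootstrap.
#' @param constants list of measured-translation constants passed to
#'   [translation_inputs()]; `var_PT_measured = NULL` means "compute from
#'   the translation tables".
#' @param var_RD,var_PD degradation variances for the measured-error
#'   shares.
#' @param out_dir optional output directory; when given, the corrected
#'   table, fitted model and report are written there.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(calibration_pairs, expression, rna_gold,
                       translation_measured = NULL,
                       translation_inferred = NULL, census = NULL,
                       strategy = c("measured-error",
                                    "measured-translation"),
                       n_boot = 999, seed = 1,
                       constants = list(sigma_MP2 = 0.97,
                                        pct_PT_inferred = 55,
                                        pct_PD_inferred = 4.9,
                                        pct_RD_inferred = 6.4,
                                        var_PT_inferred_pergene = 0.29,
                                        var_PT_measured = NULL),
                       var_RD = 0.062, var_PD = 0.048, out_dir = NULL) {
  strategy <- match.arg(strategy, several.ok = TRUE)
  structure(list(calibration_pairs = calibration_pairs,
                 expression = expression, rna_gold = rna_gold,
                 translation_measured = translation_measured,
                 translation_inferred = translation_inferred,
                 census = census, strategy = strategy, n_boot = n_boot,
                 seed = seed, constants = constants, var_RD = var_RD,
                 var_PD = var_PD, out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Chains calibration (two-part fit, bootstrap test, correction),
#' correlation comparison with prediction bands, both variance
#' decompositions, the translation-rate comparison and the gene census.
#' Optional stages whose inputs are absent are skipped with a message.
#'
#' @param config a [run_config()].
#' @return list of class `"pipeline_report"` with one element per stage
#'   plus a `manifest` (seed, package version, timestamp).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pairs <- run_stage("read-calibration",
                     read_calibration_pairs(config$calibration_pairs))
  expression <- run_stage("read-expression",
                          read_expression_table(config$expression))
  gold_rna <- run_stage("read-rna-gold", read_rna_gold(config$rna_gold))

  model <- run_stage("calibration", {
    m <- fit_segmented(pairs)
    m$lrt_pvalue <- bootstrap_lrt(pairs, n_boot = config$n_boot,
                                  seed = config$seed)$p_value
    m
  })
  corrected <- run_stage("correction", {
    ex <- expression
    ex$protein_1 <- apply_correction(model, ex$protein_1)
    ex$protein_2 <- apply_correction(model, ex$protein_2)
    ex
  })

  correlation <- run_stage("correlation", {
    mr <- rowMeans(expression[c("mrna_1", "mrna_2")])
    p_unc <- rowMeans(expression[c("protein_1", "protein_2")])
    p_cor <- rowMeans(corrected[c("protein_1", "protein_2")])
    ok <- is.finite(mr) & is.finite(p_unc) & is.finite(p_cor)
    cmp <- compare_dependent_correlations(
      pearson_log(mr[ok], p_unc[ok]), pearson_log(mr[ok], p_cor[ok]),
      pearson_log(p_unc[ok], p_cor[ok]), sum(ok))
    bands <- lapply(c(0.50, 0.95), function(lv) list(
      uncorrected = prediction_band(mr[ok], p_unc[ok], lv),
      corrected = prediction_band(mr[ok], p_cor[ok], lv)))
    names(bands) <- c("band50", "band95")
    c(list(comparison = cmp,
           median_corrected_molecules =
             10^median(c(corrected$protein_1, corrected$protein_2),
                       na.rm = TRUE)), bands)
  })

  translation <- NULL
  var_PT_measured <- config$constants$var_PT_measured
  if (!is.null(config$translation_measured) &&
      !is.null(config$translation_inferred)) {
    translation <- run_stage("translation", {
      meas <- read_translation_rates(config$translation_measured)
      inf <- read_translation_rates(config$translation_inferred)
      cmpr <- intersect_and_compare(meas, inf)
      adj <- adjust_variance_to_superset(
        cmpr$var_measured_log10, cmpr$var_inferred_log10,
        var(log10(inf$rate)))
      list(comparison = cmpr,
           fold_range_measured = central_fold_range(meas),
           fold_range_inferred = central_fold_range(inf),
           var_PT_measured_adjusted = adj)
    })
    if (is.null(var_PT_measured))
      var_PT_measured <- translation$var_PT_measured_adjusted
  } else message("translation stage skipped: no rate tables supplied")

  decomposition <- list()
  if ("measured-error" %in% config$strategy) {
    decomposition$measured_error <- run_stage("decompose-measured-error", {
      comp <- decompose_measured_error(corrected, gold_rna)
      list(components = comp,
           shares = four_step_from_measured_error(comp, config$var_RD,
                                                  config$var_PD))
    })
  }
  if ("measured-translation" %in% config$strategy) {
    if (is.null(var_PT_measured)) {
      message("measured-translation stage skipped: no measured ",
              "translation-rate variance available")
    } else {
      decomposition$measured_translation <-
        run_stage("decompose-measured-translation", {
          cons <- config$constants
          cons$var_PT_measured <- var_PT_measured
          inputs <- do.call(translation_inputs, cons)
          decompose_measured_translation(expression, gold_rna, inputs)
        })
    }
  }
  crosscheck <- NULL
  if (!is.null(decomposition$measured_error)) {
    crosscheck <- inferred_translation_variance_bound(
      decomposition$measured_error$shares,
      sigma_MP2_source = config$constants$sigma_MP2,
      pct_PT_source = config$constants$pct_PT_inferred)
  }

  census <- NULL
  if (!is.null(config$census)) {
    census <- run_stage("census", {
      tab <- read_abundance_table(config$census)
      reference <- setNames(
        10^rowMeans(expression[c("mrna_1", "mrna_2")]),
        expression$gene_id)
      has_common <- length(intersect(tab$gene_id,
                                     names(reference))) >= 10
      gene_census(tab, reference = if (has_common) reference else NULL)
    })
  } else message("census stage skipped: no abundance table supplied")

  report <- structure(
    list(model = model, corrected = corrected, correlation = correlation,
         decomposition = decomposition, crosscheck = crosscheck,
         translation = translation, census = census,
         manifest = list(seed = config$seed,
                         package_version =
                           as.character(utils::packageVersion("protcal")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Serialises the fitted calibration model and run summary as YAML and the
#' corrected expression table as TSV.
#'
#' @param report a `"pipeline_report"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(report$model)[c(
    "changepoint_log10", "lower_slope", "lower_intercept", "upper_slope",
    "upper_intercept", "cv_rmse", "single_slope", "single_intercept",
    "single_cv_rmse", "lrt_pvalue")],
    file.path(dir, "calibration_model.yaml"))
  write_expression_table(report$corrected,
                         file.path(dir, "corrected_expression.tsv"))
  summarise_shares <- function(s) if (is.null(s)) NULL else
    list(strategy = s$strategy, var_TP = s$var_TP,
         pct_mRNA = s$pct_mRNA, pct_TXN = s$pct_TXN, pct_RD = s$pct_RD,
         pct_PT = s$pct_PT, pct_PD = s$pct_PD)
  yaml::write_yaml(list(
    correlation = list(
      r_uncorrected = report$correlation$comparison$r1,
      r_corrected = report$correlation$comparison$r2,
      z = report$correlation$comparison$z,
      p_two_sided = report$correlation$comparison$p_two_sided,
      median_corrected_molecules =
        report$correlation$median_corrected_molecules),
    shares_measured_error =
      summarise_shares(report$decomposition$measured_error$shares),
    shares_measured_translation =
      summarise_shares(report$decomposition$measured_translation),
    crosscheck_translation_bound = report$crosscheck,
    census = if (is.null(report$census)) NULL else
      unclass(report$census)[c("n_HE", "n_LE", "n_NE",
                               "expressed_equivalents",
                               "nonexpressed_equivalents")],
    manifest = report$manifest), file.path(dir, "report.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("protcal pipeline report\n=======================\n")
  print(x$model)
  cat(sprintf("median corrected abundance: %.3g molecules/cell\n",
              x$correlation$median_corrected_molecules))
  print(x$correlation$comparison)
  if (!is.null(x$decomposition$measured_error)) {
    print(x$decomposition$measured_error$components)
    print(x$decomposition$measured_error$shares)
  }
  if (!is.null(x$decomposition$measured_translation))
    print(x$decomposition$measured_translation)
  if (!is.null(x$crosscheck))
    cat(sprintf("translation-variance cross-check ratio: %.2f\n",
                x$crosscheck))
  if (!is.null(x$census)) print(x$census)
  invisible(x)
}
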