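# Synthetic-data generator: produces expression tables, gold-standard
# subsets and translation-rate sets with the exact statistical structure
# the downstream analysis assumes, so every stage can be tested against
# known ground truth.

#' Parameters of the synthetic gene-expression generator
#'
#' The generative model, per gene i (all on log10 molecules/cell):
#' \deqn{MR_i \sim N(\mu_{MR}, sd_{MR}^2)}
#' \deqn{TR_i = b_R MR_i + c_R + e_{R,i}, \quad e_{R,i} \sim N(0, sd_{eR}^2)}
#' \deqn{TP_i = b\,TR_i + c + PD_i + PT_i + f_i}
#' with independent centred Gaussian deviations \eqn{PD_i} (protein
#' degradation), \eqn{PT_i} (translation) and \eqn{f_i} (residual).
#' Replicate measurements add stochastic error:
#' \eqn{MR_{ij} = MR_i + N(0, sd_{eR,rep}^2)} and
#' \eqn{MP_{ij} = TP_i + c_P + N(0, sd_{eP,rep}^2)}.  The systematic mRNA
#' error \eqn{e_R} is drawn once per gene and shared across replicates;
#' stochastic errors are drawn per replicate.
#'
#' If `compression` is a [segmented_model()], survey protein values are
#' passed through its inverse, emulating the non-linear underestimation of
#' low-abundance proteins by label-free surveys; calibrating the resulting
#' gold-standard pairs then recovers that model.
#'
#' Translation-rate sets live on their own (rate) axis: both the
#' measured-like and the inferred-like set carry signal \eqn{d\,PT_i}, with
#' light noise `sd_rate_measured` on the measured set and heavy noise
#' `sd_rate_inferred` on the inferred set, so that the inferred axis has
#' variance about \eqn{d^2 var(PT) + sd_{rate,inf}^2}.
#'
#' Defaults are tuned to the scale of a mouse fibroblast proteome survey:
#' pooled survey protein log10 variance about 0.97 (about 0.36 after
#' decompression), protein-on-mRNA correlation about 0.64, stochastic
#' protein error about 7% and systematic mRNA error about 23% of the
#' residual variance, and a corrected median abundance near 1.7e5
#' molecules/cell.
#'
#' @param n_genes number of genes.
#' @param b,c slope/intercept of true protein on true mRNA.
#' @param b_R,c_R slope/intercept of true mRNA on measured mRNA.
#' @param c_P protein measurement offset (log10).
#' @param mu_MR,sd_MR mean/sd of the measured-mRNA log10 distribution.
#' @param sd_eR systematic (per-gene) mRNA error sd.
#' @param sd_eR_rep stochastic per-replicate mRNA error sd.
#' @param sd_PD,sd_PT,sd_f sds of the degradation, translation and residual
#'   deviations entering true protein levels.
#' @param d translation scaling between the protein contribution `PT` and
#'   the translation-rate axis.
#' @param sd_eP_rep stochastic per-replicate protein error sd.
#' @param sd_ref gold-standard protein reference error sd.
#' @param sd_ref_rna gold-standard mRNA reference error sd.
#' @param n_gold_protein,n_gold_rna gold-standard subset sizes.
#' @param gold_protein_bias exponential-tilting coefficient for the gold
#'   protein subset: genes are sampled with probability proportional to
#'   \eqn{10^{bias \cdot TP}}, emulating the abundance bias of proteins
#'   with individual literature measurements (0 = uniform sampling).
#' @param n_rate_inferred,n_rate_measured,n_rate_overlap sizes of the
#'   inferred-like and measured-like translation-rate sets and of their
#'   intersection.
#' @param mu_rate_measured,mu_rate_inferred location of each rate axis
#'   (log10, arbitrary units).
#' @param sd_rate_measured,sd_rate_inferred rate measurement noise sds.
#' @param compression a [segmented_model()] describing the survey
#'   distortion, or `NULL` for none.
#' @param seed integer random seed (`NULL`: use the current RNG stream).
#' @return object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_genes = 5028,
                              b = 0.76, c = 4.295,
                              b_R = 1, c_R = 0, c_P = 0,
                              mu_MR = 1.23, sd_MR = 0.509902,
                              sd_eR = 0.292062, sd_eR_rep = 0.041110,
                              sd_PD = 0.219089, sd_PT = 0.316228,
                              sd_f = 0.044721, d = 0.5814,
                              sd_eP_rep = 0.121655,
                              sd_ref = 0.15, sd_ref_rna = 0.05,
                              n_gold_protein = 61, n_gold_rna = 79,
                              gold_protein_bias = 0.8,
                              n_rate_inferred = 3633,
                              n_rate_measured = 3352,
                              n_rate_overlap = 3126,
                              mu_rate_measured = 0, mu_rate_inferred = 0.5,
                              sd_rate_measured = 0.0316,
                              sd_rate_inferred = 0.5062,
                              compression = segmented_model(6, 0.56, 2.64,
                                                            1.06, -0.41),
                              seed = NULL) {
  p <- list(n_genes = n_genes, b = b, c = c, b_R = b_R, c_R = c_R, c_P = c_P,
            mu_MR = mu_MR, sd_MR = sd_MR, sd_eR = sd_eR,
            sd_eR_rep = sd_eR_rep, sd_PD = sd_PD, sd_PT = sd_PT,
            sd_f = sd_f, d = d, sd_eP_rep = sd_eP_rep, sd_ref = sd_ref,
            sd_ref_rna = sd_ref_rna, n_gold_protein = n_gold_protein,
            n_gold_rna = n_gold_rna, gold_protein_bias = gold_protein_bias,
            n_rate_inferred = n_rate_inferred,
            n_rate_measured = n_rate_measured,
            n_rate_overlap = n_rate_overlap,
            mu_rate_measured = mu_rate_measured,
            mu_rate_inferred = mu_rate_inferred,
            sd_rate_measured = sd_rate_measured,
            sd_rate_inferred = sd_rate_inferred,
            compression = compression, seed = seed)
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  scalars <- c("b", "c", "b_R", "c_R", "c_P", "mu_MR",
               "mu_rate_measured", "mu_rate_inferred")
  sds <- c("sd_MR", "sd_eR", "sd_eR_rep", "sd_PD", "sd_PT", "sd_f", "d",
           "sd_eP_rep", "sd_ref", "sd_ref_rna", "sd_rate_measured",
           "sd_rate_inferred")
  for (nm in scalars) check_number(p[[nm]], nm)
  check_number(p$gold_protein_bias, "gold_protein_bias", min = 0)
  for (nm in sds) check_number(p[[nm]], nm, min = 0)
  check_number(p$n_genes, "n_genes", min = 2)
  for (nm in c("n_gold_protein", "n_gold_rna")) {
    check_number(p[[nm]], nm, min = 0)
    if (p[[nm]] > p$n_genes)
      stop(sprintf("'%s' cannot exceed 'n_genes'", nm), call. = FALSE)
  }
  for (nm in c("n_rate_inferred", "n_rate_measured", "n_rate_overlap"))
    check_number(p[[nm]], nm, min = 0)
  if (p$n_rate_overlap > min(p$n_rate_inferred, p$n_rate_measured))
    stop("'n_rate_overlap' cannot exceed either rate-set size",
         call. = FALSE)
  if (max(p$n_rate_inferred, p$n_rate_measured) > p$n_genes)
    stop("translation-rate set sizes cannot exceed 'n_genes'", call. = FALSE)
  if (!is.null(p$compression) && !inherits(p$compression, "segmented_model"))
    stop("'compression' must be NULL or a segmented_model", call. = FALSE)
  invisible(p)
}

#' A set of per-gene translation rates from one source
#'
#' @param gene_id gene identifiers (unique).
#' @param rate positive rates in the source's own units.
#' @param source_label free-text label.
#' @return data.frame of class `"translation_rate_set"` with attribute
#'   `source_label`.
#' @export
translation_rate_set <- function(gene_id, rate, source_label = "") {
  if (anyDuplicated(gene_id))
    stop("translation-rate gene identifiers must be unique", call. = FALSE)
  if (!all(is.finite(rate)) || any(rate <= 0))
    stop("translation rates must be finite and > 0", call. = FALSE)
  out <- data.frame(gene_id = as.character(gene_id), rate = as.numeric(rate),
                    stringsAsFactors = FALSE)
  attr(out, "source_label") <- source_label
  class(out) <- c("translation_rate_set", "data.frame")
  out
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Draws per-gene true mRNA and protein abundances, replicate measurements,
#' gold-standard calibration subsets (protein and mRNA) and two
#' translation-rate sets under the model described in
#' [simulation_params()].
#'
#' @param params a [simulation_params()] object.
#' @return object of class `"synthetic_bundle"`: a list with elements
#'   `truth` (per-gene `TR`, `TP`, `PD`, `PT`, `f`, log10), `expression`
#'   (gene_id, `protein_1`, `protein_2`, `mrna_1`, `mrna_2`, log10, on the
#'   survey scale when compression is active), `calibration`
#'   ([calibration_pairs()] for the gold protein subset), `rna_gold`
#'   (gold vs survey mRNA pairs) and `translation` (list of `measured` and
#'   `inferred` [translation_rate_set()]s), plus the `params` used.
#' @export
generate_expression_dataset <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params"))
    params <- do.call(simulation_params, params)
  p <- params
  with_seed(p$seed, {
    n <- as.integer(p$n_genes)
    id <- sprintf("g%05d", seq_len(n))
    MR <- rnorm(n, p$mu_MR, p$sd_MR)
    eR <- rnorm(n, 0, p$sd_eR)
    TR <- p$b_R * MR + p$c_R + eR
    PD <- rnorm(n, 0, p$sd_PD)
    PT <- rnorm(n, 0, p$sd_PT)
    f  <- rnorm(n, 0, p$sd_f)
    TP <- p$b * TR + p$c + PD + PT + f

    mrna_1 <- MR + rnorm(n, 0, p$sd_eR_rep)
    mrna_2 <- MR + rnorm(n, 0, p$sd_eR_rep)
    MP_1 <- TP + p$c_P + rnorm(n, 0, p$sd_eP_rep)
    MP_2 <- TP + p$c_P + rnorm(n, 0, p$sd_eP_rep)
    if (!is.null(p$compression)) {
      protein_1 <- invert_correction(p$compression, MP_1)
      protein_2 <- invert_correction(p$compression, MP_2)
    } else {
      protein_1 <- MP_1
      protein_2 <- MP_2
    }

    truth <- data.frame(gene_id = id, TR = TR, TP = TP, PD = PD, PT = PT,
                        f = f, stringsAsFactors = FALSE)
    expression <- expression_table(id, protein_1, protein_2, mrna_1, mrna_2)

    w_gold <- 10^(p$gold_protein_bias * (TP - max(TP)))
    gold_p <- sort(sample.int(n, p$n_gold_protein, prob = w_gold))
    calibration <- calibration_pairs(
      id[gold_p],
      reference_log10 = TP[gold_p] + p$c_P + rnorm(length(gold_p), 0, p$sd_ref),
      survey_log10 = (protein_1[gold_p] + protein_2[gold_p]) / 2,
      method_tag = "synthetic-reference")

    gold_r <- sort(sample.int(n, p$n_gold_rna))
    rna_gold <- data.frame(
      gene_id = id[gold_r],
      reference_log10 = TR[gold_r] + rnorm(length(gold_r), 0, p$sd_ref_rna),
      survey_log10 = (mrna_1[gold_r] + mrna_2[gold_r]) / 2,
      stringsAsFactors = FALSE)

    inf_idx <- sort(sample.int(n, p$n_rate_inferred))
    overlap <- sort(sample(inf_idx, p$n_rate_overlap))
    pool <- setdiff(seq_len(n), inf_idx)
    extra <- sort(sample(pool, p$n_rate_measured - p$n_rate_overlap))
    meas_idx <- sort(c(overlap, extra))
    rate_meas <- p$mu_rate_measured + p$d * PT[meas_idx] +
      rnorm(length(meas_idx), 0, p$sd_rate_measured)
    rate_inf <- p$mu_rate_inferred + p$d * PT[inf_idx] +
      rnorm(length(inf_idx), 0, p$sd_rate_inferred)
    translation <- list(
      measured = translation_rate_set(id[meas_idx], 10^rate_meas,
                                      "synthetic-ribosome-profiling"),
      inferred = translation_rate_set(id[inf_idx], 10^rate_inf,
                                      "synthetic-inferred"))

    structure(list(params = p, truth = truth, expression = expression,
                   calibration = calibration, rna_gold = rna_gold,
                   translation = translation),
              class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("Synthetic expression bundle: %d genes\n", nrow(x$truth)))
  cat(sprintf("  gold protein pairs: %d, gold mRNA pairs: %d\n",
              nrow(x$calibration), nrow(x$rna_gold)))
  cat(sprintf("  translation rates: %d measured-like, %d inferred-like\n",
              nrow(x$translation$measured), nrow(x$translation$inferred)))
  cat(sprintf("  survey compression: %s\n",
              if (is.null(x$params$compression)) "none" else
                sprintf("two-part model, change point 10^%.2f",
                        x$params$compression$changepoint_log10)))
  invisible(x)
}

#' Generate a synthetic calibration set from a known two-part model
#'
#' Survey abundances are drawn uniformly over `range` (log10) and reference
#' values are the model-mapped survey values plus Gaussian noise.  With
#' `noise_sd = 0`, refitting recovers the generating model exactly.
#'
#' @param model a [segmented_model()].
#' @param n number of pairs (>= 4).
#' @param noise_sd reference noise sd, log10 units.
#' @param seed optional integer seed.
#' @param range survey log10 range to sample over.
#' @return a [calibration_pairs()] table.
#' @export
generate_calibration_set <- function(model, n, noise_sd = 0.2, seed = NULL,
                                     range = c(3, 8)) {
  stopifnot(inherits(model, "segmented_model"))
  check_number(n, "n", min = 4)
  check_number(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    survey <- sort(runif(n, range[1], range[2]))
    reference <- apply_correction(model, survey) + rnorm(n, 0, noise_sd)
    calibration_pairs(sprintf("cal%04d", seq_len(n)), reference, survey,
                      method_tag = "synthetic")
  })
}

#' Parameters of the trimodal mRNA abundance generator
#'
#' Emulates the trimodal population-average mRNA distribution of a single
#' cell type: a highly expressed (HE) log-normal mode centred near 10
#' molecules/cell, a low expressed (LE) mode centred near 0.1
#' molecules/cell, and a not-expressed (NE) class reported as undetected.
#' Mode fractions refer to generator components; class counts reported by
#' [classify_expression()] arise from the one-molecule-per-cell threshold
#' and therefore also include the tails of each mode.
#'
#' The default fractions and mode shapes are matched to a census of 21,309
#' genes with 15,325 detected (11,301 at or above one molecule per cell)
#' and 5,984 undetected.
#'
#' @param n_genes number of genes.
#' @param frac_NE fraction of genes undetected.
#' @param frac_LE fraction of genes in the low-expression component.
#' @param mu_LE,sd_LE log10 molecules/cell mean and sd of the LE mode.
#' @param mu_HE,sd_HE log10 molecules/cell mean and sd of the HE mode.
#' @param seed optional integer seed.
#' @return object of class `"trimodal_params"`.
#' @export
trimodal_params <- function(n_genes = 21309, frac_NE = 0.280820,
                            frac_LE = 0.111754, mu_LE = -1, sd_LE = 0.55,
                            mu_HE = 1, sd_HE = 0.9, seed = NULL) {
  check_number(n_genes, "n_genes", min = 1)
  check_number(frac_NE, "frac_NE", min = 0)
  check_number(frac_LE, "frac_LE", min = 0)
  if (frac_NE > 1 || frac_LE > 1 || frac_NE + frac_LE > 1)
    stop("'frac_NE' and 'frac_LE' must lie in [0, 1] and sum to <= 1",
         call. = FALSE)
  check_number(mu_LE, "mu_LE"); check_number(mu_HE, "mu_HE")
  check_number(sd_LE, "sd_LE", min = 0); check_number(sd_HE, "sd_HE", min = 0)
  structure(list(n_genes = n_genes, frac_NE = frac_NE, frac_LE = frac_LE,
                 mu_LE = mu_LE, sd_LE = sd_LE, mu_HE = mu_HE, sd_HE = sd_HE,
                 seed = seed),
            class = "trimodal_params")
}

#' Generate a trimodal population mRNA abundance table
#'
#' @param params a [trimodal_params()] object.
#' @return data.frame with `gene_id` and `abundance` (linear molecules per
#'   cell; `NA` marks undetected genes).
#' @export
generate_trimodal_mrna <- function(params = trimodal_params()) {
  stopifnot(inherits(params, "trimodal_params"))
  p <- params
  with_seed(p$seed, {
    n <- as.integer(p$n_genes)
    n_NE <- round(p$frac_NE * n)
    n_LE <- round(p$frac_LE * n)
    n_HE <- n - n_NE - n_LE
    ab <- c(rep(NA_real_, n_NE),
            10^rnorm(n_LE, p$mu_LE, p$sd_LE),
            10^rnorm(n_HE, p$mu_HE, p$sd_HE))
    data.frame(gene_id = sprintf("t%05d", seq_len(n)),
               abundance = ab[sample.int(n)], stringsAsFactors = FALSE)
  })
}
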