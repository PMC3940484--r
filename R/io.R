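# Table input/output.  All tables travel as TSV with a header line;
# abundances are written in linear molecules/cell with the literal token
# NA (case-sensitive) marking undetected values, and are log10-transformed
# on read.  Internally every abundance is log10 molecules/cell.

EXPRESSION_COLUMNS <- c("gene_id", "protein_1", "protein_2",
                        "mrna_1", "mrna_2")

#' Construct an expression table
#'
#' Per-gene protein and mRNA abundance replicates on the log10
#' molecules-per-cell scale.  `NA` marks undetected values.
#'
#' @param gene_id gene identifiers (unique).
#' @param protein_1,protein_2 protein abundance replicates (log10).
#' @param mrna_1,mrna_2 mRNA abundance replicates (log10).
#' @return data.frame of class `"expression_table"`.
#' @export
expression_table <- function(gene_id, protein_1, protein_2, mrna_1, mrna_2) {
  if (anyDuplicated(gene_id))
    stop("gene identifiers must be unique", call. = FALSE)
  out <- data.frame(gene_id = as.character(gene_id),
                    protein_1 = as.numeric(protein_1),
                    protein_2 = as.numeric(protein_2),
                    mrna_1 = as.numeric(mrna_1),
                    mrna_2 = as.numeric(mrna_2),
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

# Parse a numeric TSV column that may contain the literal token NA.
# Reports the 1-based data line number of the first malformed entry.
parse_abundance_column <- function(txt, column, path) {
  txt <- trimws(txt)
  val <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(val) & txt != "NA")
  if (length(bad))
    stop(sprintf("malformed numeric value '%s' in column '%s' of %s (line %d)",
                 txt[bad[1]], column, path, bad[1] + 1L), call. = FALSE)
  val
}

read_tsv_columns <- function(path, required) {
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  raw
}

# Linear molecules/cell -> log10; non-positive values are flagged
# undetected (NA) alongside explicit NA tokens.
linear_to_log10 <- function(x) ifelse(is.na(x) | x <= 0, NA_real_, log10(x))

#' Read an expression table from TSV
#'
#' Expects columns `gene_id`, `protein_1`, `protein_2`, `mrna_1`, `mrna_2`
#' in linear molecules/cell.  Positive abundances are log10-transformed;
#' zeros, negative values and `NA` tokens are flagged undetected.  Row and
#' undetected counts are reported via `message()`.
#'
#' @param path TSV file path.
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path) {
  raw <- read_tsv_columns(path, EXPRESSION_COLUMNS)
  cols <- lapply(setdiff(EXPRESSION_COLUMNS, "gene_id"), function(cn)
    linear_to_log10(parse_abundance_column(raw[[cn]], cn, path)))
  names(cols) <- setdiff(EXPRESSION_COLUMNS, "gene_id")
  out <- expression_table(raw$gene_id, cols$protein_1, cols$protein_2,
                          cols$mrna_1, cols$mrna_2)
  n_und <- sum(vapply(cols, function(v) sum(is.na(v)), integer(1)))
  message(sprintf("read %d genes from %s (%d undetected entries)",
                  nrow(out), path, n_und))
  out
}

#' Write an expression table to TSV
#'
#' Values are written in linear molecules/cell with `NA` marking
#' undetected abundances.
#'
#' @param table an [expression_table()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_expression_table <- function(table, path) {
  out <- data.frame(gene_id = table$gene_id,
                    lapply(table[setdiff(EXPRESSION_COLUMNS, "gene_id")],
                           function(v) 10^v),
                    stringsAsFactors = FALSE)
  write.table(format(out, digits = 15, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read calibration pairs from TSV
#'
#' Expects columns `gene_id`, `reference`, `survey` (linear molecules per
#' cell; an optional `method_tag` column is carried through).
#'
#' @param path TSV file path.
#' @return a [calibration_pairs()] table.
#' @export
read_calibration_pairs <- function(path) {
  raw <- read_tsv_columns(path, c("gene_id", "reference", "survey"))
  reference <- parse_abundance_column(raw$reference, "reference", path)
  survey <- parse_abundance_column(raw$survey, "survey", path)
  if (any(is.na(reference)) || any(reference <= 0) ||
      any(is.na(survey)) || any(survey <= 0))
    stop(sprintf("calibration pairs in %s must be positive and non-missing",
                 path), call. = FALSE)
  tag <- if ("method_tag" %in% names(raw)) raw$method_tag else NA_character_
  calibration_pairs(raw$gene_id, log10(reference), log10(survey), tag)
}

#' @rdname read_calibration_pairs
#' @param pairs a [calibration_pairs()] table.
#' @export
write_calibration_pairs <- function(pairs, path) {
  out <- data.frame(gene_id = pairs$gene_id,
                    reference = 10^pairs$reference_log10,
                    survey = 10^pairs$survey_log10,
                    method_tag = pairs$method_tag,
                    stringsAsFactors = FALSE)
  write.table(format(out, digits = 15, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a translation-rate table from TSV
#'
#' Expects columns `gene_id` and `rate` (positive, source units); an
#' optional `source` column labels the set.
#'
#' @param path TSV file path.
#' @return a [translation_rate_set()].
#' @export
read_translation_rates <- function(path) {
  raw <- read_tsv_columns(path, c("gene_id", "rate"))
  rate <- parse_abundance_column(raw$rate, "rate", path)
  label <- if ("source" %in% names(raw)) raw$source[1] else ""
  translation_rate_set(raw$gene_id, rate, label)
}

#' @rdname read_translation_rates
#' @param rates a [translation_rate_set()].
#' @export
write_translation_rates <- function(rates, path) {
  out <- data.frame(gene_id = rates$gene_id, rate = rates$rate,
                    source = attr(rates, "source_label"),
                    stringsAsFactors = FALSE)
  write.table(format(out, digits = 15, trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population mRNA abundance table for the gene census
#'
#' Expects columns `gene_id` and `abundance` (linear units such as RPKM or
#' molecules/cell; `NA` marks undetected genes).
#'
#' @param path TSV file path.
#' @return data.frame with `gene_id` and linear `abundance`.
#' @export
read_abundance_table <- function(path) {
  raw <- read_tsv_columns(path, c("gene_id", "abundance"))
  data.frame(gene_id = raw$gene_id,
             abundance = parse_abundance_column(raw$abundance, "abundance",
                                                path),
             stringsAsFactors = FALSE)
}

#' @rdname read_abundance_table
#' @param table data.frame with `gene_id` and `abundance`.
#' @export
write_abundance_table <- function(table, path) {
  write.table(format(table[c("gene_id", "abundance")], digits = 15,
                     trim = TRUE, scientific = NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

params_to_list <- function(p) {
  out <- unclass(p)
  if (!is.null(out$compression))
    out$compression <- unclass(out$compression)[c(
      "changepoint_log10", "lower_slope", "lower_intercept",
      "upper_slope", "upper_intercept")]
  out$seed <- if (is.null(out$seed)) NA else out$seed
  out
}

#' Write simulation parameters to a YAML sidecar
#'
#' @param params a [simulation_params()] object.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "simulation_params"))
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' Read simulation parameters from a YAML sidecar
#'
#' @param path YAML path written by [write_params()].
#' @return a [simulation_params()] object.
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  if (!is.null(p$compression))
    p$compression <- do.call(segmented_model, p$compression)
  if (length(p$seed) && is.na(p$seed)) p$seed <- NULL
  do.call(simulation_params, p)
}

#' Write a synthetic bundle as a directory of TSV tables
#'
#' Writes `expression.tsv`, `calibration_pairs.tsv`, `rna_gold.tsv`,
#' `translation_measured.tsv`, `translation_inferred.tsv`, `truth.tsv` and
#' a `params.yaml` sidecar recording the generator parameters.
#'
#' @param bundle a `"synthetic_bundle"` from
#'   [generate_expression_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(bundle$expression, file.path(dir, "expression.tsv"))
  write_calibration_pairs(bundle$calibration,
                          file.path(dir, "calibration_pairs.tsv"))
  rg <- data.frame(gene_id = bundle$rna_gold$gene_id,
                   reference = 10^bundle$rna_gold$reference_log10,
                   survey = 10^bundle$rna_gold$survey_log10)
  write.table(format(rg, digits = 15, trim = TRUE, scientific = NA),
              file.path(dir, "rna_gold.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_translation_rates(bundle$translation$measured,
                          file.path(dir, "translation_measured.tsv"))
  write_translation_rates(bundle$translation$inferred,
                          file.path(dir, "translation_inferred.tsv"))
  write.table(format(bundle$truth, digits = 15, trim = TRUE),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_params(bundle$params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read gold-standard mRNA pairs from TSV
#'
#' Expects columns `gene_id`, `reference`, `survey` (linear units).
#'
#' @param path TSV file path.
#' @return data.frame with `gene_id`, `reference_log10`, `survey_log10`.
#' @export
read_rna_gold <- function(path) {
  raw <- read_tsv_columns(path, c("gene_id", "reference", "survey"))
  reference <- parse_abundance_column(raw$reference, "reference", path)
  survey <- parse_abundance_column(raw$survey, "survey", path)
  data.frame(gene_id = raw$gene_id,
             reference_log10 = log10(reference),
             survey_log10 = log10(survey), stringsAsFactors = FALSE)
}
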