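# Trimodal gene census: classify genes into highly expressed (HE), low
# expressed (LE) and not expressed (NE) classes from a population mRNA
# abundance table, and split LE genes into expressed / non-expressed
# gene-equivalents.

#' Match the scale of one abundance distribution to a reference
#'
#' Fits, on the log10 abundances of the genes common to both tables, the
#' affine transform that gives the target distribution the same median and
#' variance as the reference, and applies that transform to every detected
#' gene of the target.  Undetected (`NA`) genes pass through unchanged.
#'
#' @param target_abundances named numeric vector (names = gene ids) of
#'   linear abundances (e.g. RPKM), `NA` for undetected.
#' @param reference_abundances named numeric vector of linear reference
#'   abundances (molecules/cell).
#' @param common_ids gene identifiers used to fit the transform; defaults
#'   to all names shared by the two vectors, restricted to genes detected
#'   in both.
#' @return numeric vector like `target_abundances`, rescaled to reference
#'   units; attributes `scale` and `shift` record the log10 transform
#'   `y = scale * x + shift`.
#' @export
match_scale <- function(target_abundances, reference_abundances,
                        common_ids = NULL) {
  if (is.null(names(target_abundances)) ||
      is.null(names(reference_abundances)))
    stop("abundance vectors must be named by gene identifier", call. = FALSE)
  if (is.null(common_ids))
    common_ids <- intersect(names(target_abundances),
                            names(reference_abundances))
  t_all <- log10(target_abundances)
  r_all <- log10(reference_abundances)
  tc <- t_all[common_ids]; rc <- r_all[common_ids]
  ok <- is.finite(tc) & is.finite(rc)
  if (sum(ok) < 10)
    stop("fewer than 10 common detected genes to fit the scale transform",
         call. = FALSE)
  tc <- tc[ok]; rc <- rc[ok]
  sd_t <- sd(tc); sd_r <- sd(rc)
  if (sd_t == 0 || sd_r == 0)
    stop("zero variance among common genes: cannot match scales",
         call. = FALSE)
  scale <- sd_r / sd_t
  shift <- median(rc) - scale * median(tc)
  out <- 10^(scale * t_all + shift)
  attr(out, "scale") <- scale
  attr(out, "shift") <- shift
  out
}

#' Classify genes into HE / LE / NE expression classes
#'
#' Highly expressed (HE): one or more mRNA molecule per cell; low
#' expressed (LE): detected but below one molecule per cell; not
#' expressed (NE): undetected (`NA`).  The LE/NE boundary follows the
#' explicit undetected flag, not a numeric cutoff.
#'
#' @param abundances linear molecules/cell, `NA` for undetected.
#' @return list with counts `n_HE`, `n_LE`, `n_NE` and the logical index
#'   vectors `is_HE`, `is_LE`, `is_NE`.
#' @export
classify_expression <- function(abundances) {
  if (!is.numeric(abundances) || !length(abundances))
    stop("'abundances' must be a numeric vector", call. = FALSE)
  if (any(abundances < 0, na.rm = TRUE))
    stop("negative abundances are not valid molecule counts", call. = FALSE)
  is_NE <- is.na(abundances)
  is_HE <- !is_NE & abundances >= 1
  is_LE <- !is_NE & abundances < 1
  list(n_HE = sum(is_HE), n_LE = sum(is_LE), n_NE = sum(is_NE),
       is_HE = is_HE, is_LE = is_LE, is_NE = is_NE)
}

#' Split low-expressed genes into gene-equivalents
#'
#' Each LE gene, present at `a < 1` molecules per cell on population
#' average, is decomposed into a fraction `w = a` of a gene expressed at
#' exactly one molecule per cell and a fraction `1 - w` not expressed in
#' any cell.  This is the unique split conserving the expected molecule
#' count (`w * 1 + (1 - w) * 0 = a`).
#'
#' @param le_abundances linear molecules/cell of the LE genes, each in
#'   (0, 1); values >= 1 are dropped with a warning (they belong to HE).
#' @return list with `le_weights`, `expressed_equivalents` (sum of w) and
#'   `nonexpressed_equivalents` (sum of 1 - w).
#' @export
split_le <- function(le_abundances) {
  check_finite_vector(le_abundances, "le_abundances")
  if (any(le_abundances <= 0))
    stop("LE abundances must be positive", call. = FALSE)
  high <- le_abundances >= 1
  if (any(high)) {
    warning(sprintf("%d abundance(s) >= 1 molecule/cell belong to HE and were dropped",
                    sum(high)))
    le_abundances <- le_abundances[!high]
  }
  w <- le_abundances
  list(le_weights = w, expressed_equivalents = sum(w),
       nonexpressed_equivalents = sum(1 - w))
}

#' Trimodal gene census
#'
#' Classifies genes into HE / LE / NE (optionally after matching the
#' table's scale to a reference with [match_scale()]) and splits the LE
#' class into expressed and non-expressed gene-equivalents.  Total
#' gene-equivalents are conserved exactly:
#' `expressed + nonexpressed = n_HE + n_LE + n_NE`.
#'
#' @param abundance_table data.frame with `gene_id` and linear `abundance`
#'   (`NA` = undetected), e.g. from [read_abundance_table()] or
#'   [generate_trimodal_mrna()].
#' @param reference optional named vector of reference abundances
#'   (molecules/cell) for scale matching.
#' @return object of class `"expression_census"`.
#' @export
gene_census <- function(abundance_table, reference = NULL) {
  ab <- abundance_table$abundance
  names(ab) <- abundance_table$gene_id
  if (!is.null(reference)) ab <- match_scale(ab, reference)
  cls <- classify_expression(as.numeric(ab))
  le <- if (cls$n_LE > 0) split_le(as.numeric(ab)[cls$is_LE]) else
    list(le_weights = numeric(0), expressed_equivalents = 0,
         nonexpressed_equivalents = 0)
  structure(list(n_HE = cls$n_HE, n_LE = cls$n_LE, n_NE = cls$n_NE,
                 le_weights = le$le_weights,
                 expressed_equivalents = cls$n_HE +
                   le$expressed_equivalents,
                 nonexpressed_equivalents = cls$n_NE +
                   le$nonexpressed_equivalents),
            class = "expression_census")
}

#' @export
print.expression_census <- function(x, ...) {
  cat("Trimodal expression census\n")
  cat(sprintf("  HE (>= 1 molecule/cell): %d genes\n", x$n_HE))
  cat(sprintf("  LE (detected, < 1)     : %d genes\n", x$n_LE))
  cat(sprintf("  NE (undetected)        : %d genes\n", x$n_NE))
  cat(sprintf("  expressed gene-equivalents    : %.0f\n",
              x$expressed_equivalents))
  cat(sprintf("  non-expressed gene-equivalents: %.0f\n",
              x$nonexpressed_equivalents))
  invisible(x)
}
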