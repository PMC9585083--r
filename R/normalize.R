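#' Quantile-normalize a count matrix
#'
#' Forces every sample (column) to share one reference distribution: the
#' vector of row-wise means of the column-sorted matrix. Ties within a column
#' receive the mean of the reference values at their tied ranks.
#'
#' @param x Feature matrix tibble (`feature_id` + one numeric column per
#'   sample), raw non-negative values.
#' @return A tibble of the same shape with quantile-normalized values.
#' @examples
#' x <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                     s1 = c(1, 2, 3), s2 = c(2, 4, 6))
#' quantile_normalize(x)
#' @export
quantile_normalize <- function(x) {
  fm_validate(x, require_nonneg = TRUE)
  m <- fm_matrix(x)
  if (ncol(m) < 2L) {
    abort("Quantile normalization needs at least 2 samples.")
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  fm_tibble(out)
}

#' Trimmed-mean (TMM) scale factors
#'
#' Per-sample scale factors from the trimmed mean of M-values, the internal
#' normalization of the edgeR pipeline: pairwise log-ratios against a
#' reference sample (the column whose 75th-percentile count is closest to the
#' mean of all columns' 75th percentiles) are trimmed on both the log-ratio
#' and abundance axes and averaged with precision weights. Factors are
#' anchored so their geometric mean is 1. A pure sequencing-depth difference
#' between two samples is absorbed entirely by the library sizes, leaving
#' both TMM factors at 1.
#'
#' @param x Feature matrix tibble of raw or quantile-normalized counts.
#' @param trim_logratio Two-sided trim fraction on log-ratios.
#' @param trim_abundance Two-sided trim fraction on average abundance.
#' @return A tibble with one row per sample: `sample_id`, `lib_size` (column
#'   sum), `norm_factor` (TMM factor, geometric mean 1), `effective_lib_size`
#'   (`lib_size * norm_factor`) and `scale_factor` (effective library size
#'   rescaled to geometric mean 1; divide counts by it to normalize).
#' @export
trimmed_mean_scale <- function(x, trim_logratio = 0.3, trim_abundance = 0.05) {
  fm_validate(x, require_nonneg = TRUE)
  m <- fm_matrix(x)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("Sample(s) with all-zero counts: %s.",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = trim_logratio,
                              sumTrim = trim_abundance)
  eff <- lib * f
  tibble(sample_id = colnames(m),
         lib_size = unname(lib),
         norm_factor = unname(f),
         effective_lib_size = unname(eff),
         scale_factor = unname(eff / geometric_mean(eff)))
}

#' Normalize counts the way the paired RNA pipeline does
#'
#' Applies quantile normalization and/or trimmed-mean scaling, in that order.
#' After quantile normalization all columns already share a distribution, so
#' the subsequent TMM factors are close to 1; the switch exists because the
#' two stages answer different questions (distribution shape vs composition
#' bias) and either can be run alone.
#'
#' @param x Raw feature matrix tibble.
#' @param method `"quantile"`, `"tmm"`, or `"quantile+tmm"` (default).
#' @inheritParams trimmed_mean_scale
#' @return Normalized feature matrix tibble.
#' @export
normalize_counts <- function(x, method = c("quantile+tmm", "quantile", "tmm"),
                             trim_logratio = 0.3, trim_abundance = 0.05) {
  method <- arg_match(method)
  out <- x
  if (method %in% c("quantile", "quantile+tmm")) {
    out <- quantile_normalize(out)
  }
  if (method %in% c("tmm", "quantile+tmm")) {
    fac <- trimmed_mean_scale(out, trim_logratio, trim_abundance)
    m <- fm_matrix(out)
    m <- sweep(m, 2L, fac$scale_factor[match(colnames(m), fac$sample_id)], "/")
    out <- fm_tibble(m)
  }
  out
}

#' Median-scale peptide intensities
#'
#' Multiplies each sample by (global median of per-sample medians) / (that
#' sample's median), computed over observed peptides only (zeros are treated
#' as missing). Afterwards every sample's median observed intensity is equal.
#'
#' @param x Feature matrix tibble of raw peptide intensities; zeros denote
#'   unobserved peptides and are left at zero.
#' @return Scaled feature matrix tibble.
#' @export
median_scale_peptides <- function(x) {
  fm_validate(x, require_nonneg = TRUE)
  m <- fm_matrix(x)
  obs <- m
  obs[obs == 0] <- NA_real_
  meds <- apply(obs, 2L, median, na.rm = TRUE)
  if (any(is.na(meds))) {
    abort(sprintf("Sample(s) with no observed peptides: %s.",
                  paste(colnames(m)[is.na(meds)], collapse = ", ")))
  }
  target <- median(meds)
  out <- sweep(m, 2L, target / meds, "*")
  fm_tibble(out)
}

#' Sum peptide intensities to protein level
#'
#' Protein quantification by summation of the (already median-scaled)
#' intensities of its peptides. Peptides mapped to more than one protein are
#' an error: shared peptides must be resolved before quantification. Proteins
#' none of whose peptides were observed in any sample are dropped.
#'
#' @param x Scaled peptide intensity tibble (`feature_id` = peptide id).
#' @param mapping Tibble with columns `peptide_id`, `protein_id` covering
#'   every peptide in `x`.
#' @return Protein-level feature matrix tibble (`feature_id` = protein id).
#'   Column sums equal those of the peptide matrix restricted to mapped
#'   peptides.
#' @export
sum_peptides_to_proteins <- function(x, mapping) {
  fm_validate(x, require_nonneg = TRUE)
  if (!all(c("peptide_id", "protein_id") %in% names(mapping))) {
    abort("`mapping` needs columns `peptide_id` and `protein_id`.")
  }
  shared <- mapping %>%
    distinct(.data$peptide_id, .data$protein_id) %>%
    count(.data$peptide_id) %>%
    filter(.data$n > 1L)
  if (nrow(shared)) {
    abort(sprintf("Peptide(s) mapped to multiple proteins: %s. Resolve shared peptides upstream.",
                  paste(head(shared$peptide_id, 5L), collapse = ", ")))
  }
  unmapped <- setdiff(x$feature_id, mapping$peptide_id)
  if (length(unmapped)) {
    abort(sprintf("Peptide(s) missing from mapping: %s.",
                  paste(head(unmapped, 5L), collapse = ", ")))
  }
  long <- x %>%
    left_join(distinct(mapping, .data$peptide_id, .data$protein_id),
              by = c(feature_id = "peptide_id")) %>%
    select(-"feature_id") %>%
    rename(feature_id = "protein_id") %>%
    group_by(.data$feature_id) %>%
    summarise(across(everything(), sum), .groups = "drop")
  keep <- rowSums(as.matrix(long[, -1, drop = FALSE])) > 0
  long[keep, , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (wraps
#' [stats::p.adjust()] after validating the inputs are proper p-values).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, capped at 1, same order as the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("`pvalues` must be finite numbers in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}
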