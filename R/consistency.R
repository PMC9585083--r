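#' Per-pair log2 fold changes
#'
#' For every patient pair, `log2((treated + pseudocount) / (control +
#' pseudocount))` per feature, treated over control. The pseudocount guards
#' against zeros in normalized counts.
#'
#' @param x Normalized feature matrix tibble.
#' @param samples Sample sheet tibble (`sample_id`, `patient_id`,
#'   `condition`); every patient must have exactly one `control` and one
#'   `treated` sample among the matrix columns.
#' @param pseudocount Added to numerator and denominator before the ratio.
#' @return A tibble with `feature_id` plus one log2FC column per patient
#'   (named by `patient_id`); the pairing used is attached as attribute
#'   `"pairs"`.
#' @examples
#' x <- tibble::tibble(feature_id = "g1", A_EV = 0, A_N1 = 7)
#' sheet <- tibble::tibble(sample_id = c("A_EV", "A_N1"),
#'                         patient_id = "A",
#'                         condition = c("control", "treated"))
#' pairwise_log2fc(x, sheet)  # log2(8/1) = 3
#' @export
pairwise_log2fc <- function(x, samples, pseudocount = 1.0) {
  fm_validate(x)
  check_scalar_number(pseudocount, "pseudocount", lower = 0)
  pairs <- resolve_pairs(samples)
  missing_samples <- setdiff(c(pairs$control_sample, pairs$treated_sample),
                             fm_samples(x))
  if (length(missing_samples)) {
    abort(sprintf("Sample(s) in the sheet but not in the matrix: %s.",
                  paste(missing_samples, collapse = ", ")))
  }
  m <- fm_matrix(x)
  fc <- log2((m[, pairs$treated_sample, drop = FALSE] + pseudocount) /
               (m[, pairs$control_sample, drop = FALSE] + pseudocount))
  colnames(fc) <- pairs$patient_id
  out <- fm_tibble(fc)
  attr(out, "pairs") <- pairs
  out
}

#' Fold-change consistency criterion
#'
#' The threshold rule deciding whether a feature is consistently up- or
#' down-regulated across patient pairs. A feature is called up when the
#' number of pairs with log2FC above `fc_threshold` is at least
#' `ceiling(min_fraction * n_pairs)`; optionally all pairs must additionally
#' agree in sign, and/or the mean log2FC must exceed the threshold. When
#' `require_mean_threshold` is set the per-pair exceedance count is replaced
#' by the mean test (the proteomics rule: mean beyond the threshold with all
#' pairs sign-consistent). Down-calls are symmetric.
#'
#' @param fc_threshold Positive log2 fold-change threshold.
#' @param min_fraction Fraction of pairs that must exceed the threshold
#'   ("at least half" = 0.5; with an odd pair count this means
#'   `>= ceiling(n/2)`).
#' @param require_all_same_sign All pairs must share the call's sign.
#' @param require_mean_threshold Test the mean log2FC against the threshold
#'   instead of counting per-pair exceedances.
#' @return A `consistency_criterion` object.
#' @export
consistency_criterion <- function(fc_threshold = 0.5, min_fraction = 0.5,
                                  require_all_same_sign = FALSE,
                                  require_mean_threshold = FALSE) {
  check_scalar_number(fc_threshold, "fc_threshold", lower = 0, strict_lower = TRUE)
  check_scalar_number(min_fraction, "min_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  structure(list(fc_threshold = fc_threshold,
                 min_fraction = min_fraction,
                 require_all_same_sign = isTRUE(require_all_same_sign),
                 require_mean_threshold = isTRUE(require_mean_threshold)),
            class = "consistency_criterion")
}

#' Preset consistency criteria
#'
#' * `standard`: log2FC beyond +/-0.5 in at least half of the pairs.
#' * `stringent`: the standard rule plus the same sign in all pairs (used for
#'   genotype-stratified calls, where fewer pairs demand stronger agreement).
#' * `protein`: mean log2FC beyond +/-0.5 with all pairs sign-consistent
#'   (the three-patient proteomics rule).
#'
#' @param name One of `"standard"`, `"stringent"`, `"protein"`.
#' @param fc_threshold Log2 threshold shared by all presets.
#' @return A [consistency_criterion()].
#' @export
de_criterion <- function(name = c("standard", "stringent", "protein"),
                         fc_threshold = 0.5) {
  name <- arg_match(name)
  switch(name,
    standard = consistency_criterion(fc_threshold, 0.5, FALSE, FALSE),
    stringent = consistency_criterion(fc_threshold, 0.5, TRUE, FALSE),
    protein = consistency_criterion(fc_threshold, 1, TRUE, TRUE)
  )
}

#' Call consistently regulated features across patient pairs
#'
#' Applies a [consistency_criterion()] to a per-pair log2 fold-change table.
#' Features satisfying the up rule are `up`, the mirrored rule `down`;
#' features satisfying both (possible with four or more pairs and mixed
#' large effects) are flagged as conflicts and left `not_called`.
#'
#' @param fc Per-pair log2FC tibble from [pairwise_log2fc()].
#' @param criterion A [consistency_criterion()] (default: the standard rule).
#' @return A tibble with one row per feature: `feature_id`, `direction`
#'   (`up` / `down` / `not_called`), `n_pairs_passing` (pairs beyond the
#'   threshold in the called direction; the larger of the two counts for
#'   uncalled features), `mean_log2fc`, `conflict`.
#' @export
call_consistency <- function(fc, criterion = de_criterion("standard")) {
  fm_validate(fc)
  stopifnot(inherits(criterion, "consistency_criterion"))
  m <- fm_matrix(fc)
  if (ncol(m) < 1L) abort("`fc` has no pair columns.")
  n_pairs <- ncol(m)
  need <- as.integer(ceiling(criterion$min_fraction * n_pairs))

  up_count <- rowSums(m > criterion$fc_threshold)
  down_count <- rowSums(m < -criterion$fc_threshold)
  mean_fc <- rowMeans(m)

  up_ok <- if (criterion$require_mean_threshold) {
    mean_fc > criterion$fc_threshold
  } else {
    up_count >= need
  }
  down_ok <- if (criterion$require_mean_threshold) {
    mean_fc < -criterion$fc_threshold
  } else {
    down_count >= need
  }
  if (criterion$require_all_same_sign) {
    up_ok <- up_ok & rowSums(m > 0) == n_pairs
    down_ok <- down_ok & rowSums(m < 0) == n_pairs
  }

  conflict <- up_ok & down_ok
  direction <- rep("not_called", nrow(m))
  direction[up_ok & !conflict] <- "up"
  direction[down_ok & !conflict] <- "down"

  passing <- ifelse(direction == "up", up_count,
                    ifelse(direction == "down", down_count,
                           pmax(up_count, down_count)))
  tibble(feature_id = rownames(m),
         direction = factor(direction, levels = c("up", "down", "not_called")),
         n_pairs_passing = as.integer(passing),
         mean_log2fc = unname(mean_fc),
         conflict = unname(conflict))
}

#' Proteomics consistency call
#'
#' The three-patient protein rule: mean log2FC beyond +/-`fc_threshold` with
#' every pair agreeing in sign. Equivalent to [call_consistency()] with the
#' `protein` preset.
#'
#' @inheritParams call_consistency
#' @param fc_threshold Log2 threshold on the mean fold change.
#' @export
call_protein_consistency <- function(fc, fc_threshold = 0.5) {
  call_consistency(fc, de_criterion("protein", fc_threshold))
}
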