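# Internal helpers shared across modules.

# A feature matrix travels as a tibble whose first column is `feature_id`
# (character, unique) and whose remaining columns are numeric, one per sample.

fm_validate <- function(x, require_nonneg = FALSE, arg = caller_arg(x)) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame (feature_id + sample columns).", arg))
  }
  if (ncol(x) < 2L || names(x)[1] != "feature_id") {
    abort(sprintf("`%s` must have `feature_id` as its first column plus sample columns.", arg))
  }
  if (anyDuplicated(x$feature_id)) {
    abort(sprintf("`%s` has duplicated feature ids.", arg))
  }
  sample_cols <- names(x)[-1]
  if (anyDuplicated(sample_cols)) {
    abort(sprintf("`%s` has duplicated sample columns.", arg))
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    abort(sprintf("Sample columns of `%s` must be numeric.", arg))
  }
  if (any(!is.finite(vals))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (require_nonneg && any(vals < 0)) {
    abort(sprintf("`%s` must be non-negative.", arg))
  }
  invisible(x)
}

fm_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

fm_tibble <- function(m) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
  out
}

fm_samples <- function(x) names(x)[-1]

# Sample sheet: tibble with sample_id, patient_id, condition (+ optional genotype)
sheet_validate <- function(sheet, conditions = c("control", "treated"),
                           arg = caller_arg(sheet)) {
  needed <- c("sample_id", "patient_id", "condition")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  dup <- sheet %>%
    count(.data$patient_id, .data$condition) %>%
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("`%s`: patient/condition combinations occur more than once: %s.",
                  arg, paste(dup$patient_id, dup$condition, sep = "/", collapse = ", ")))
  }
  invisible(sheet)
}

# Resolve patient pairs: one control + one treated sample per patient.
resolve_pairs <- function(sheet, conditions = c("control", "treated")) {
  sheet_validate(sheet, conditions)
  keep <- sheet %>% filter(.data$condition %in% conditions)
  pairs <- keep %>%
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "condition",
                       values_from = "sample_id")
  for (cond in conditions) {
    if (!cond %in% names(pairs)) pairs[[cond]] <- NA_character_
    bad <- pairs$patient_id[is.na(pairs[[cond]])]
    if (length(bad)) {
      abort(sprintf("Patient(s) missing a '%s' sample: %s.",
                    cond, paste(bad, collapse = ", ")))
    }
  }
  tibble(patient_id = as.character(pairs$patient_id),
         control_sample = pairs[[conditions[1]]],
         treated_sample = pairs[[conditions[2]]])
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
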