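#' Compare construct-induced effects between two genotype groups
#'
#' For two genotype-stratified analyses (e.g. trisomy-12 vs del(13q)
#' patients), relates the mean per-pair log2 fold changes of each group's
#' called features: a scatter of group-A mean vs group-B mean over the union
#' of called features, the Pearson correlation over that union, and a
#' least-squares slope (with 95% confidence band) fitted separately to each
#' feature set. Features called in both groups with the same direction form
#' the `common` set.
#'
#' @param fc_a,fc_b Per-pair log2FC tibbles ([pairwise_log2fc()]) for the two
#'   groups; features are matched by `feature_id`.
#' @param calls_a,calls_b Consistency-call tibbles ([call_consistency()]) for
#'   the two groups.
#' @param labels Length-2 character labels for the groups.
#' @return A `genotype_comparison` object: `scatter` (feature_id, mean log2FC
#'   in each group, set membership), `pearson_r` (over the union; `NA` with
#'   fewer than 3 features), `slopes` (per set: slope, 95% band, n),
#'   `labels`.
#' @export
compare_genotype_effects <- function(fc_a, calls_a, fc_b, calls_b,
                                     labels = c("groupA", "groupB")) {
  fm_validate(fc_a, arg = "fc_a"); fm_validate(fc_b, arg = "fc_b")
  stopifnot(length(labels) == 2L)
  called_a <- calls_a$feature_id[calls_a$direction != "not_called"]
  called_b <- calls_b$feature_id[calls_b$direction != "not_called"]
  if (length(called_a) < 3L || length(called_b) < 3L) {
    abort("Each group needs at least 3 called features.")
  }

  shared_universe <- intersect(fc_a$feature_id, fc_b$feature_id)
  mean_a <- rowMeans(fm_matrix(fc_a))[shared_universe]
  mean_b <- rowMeans(fm_matrix(fc_b))[shared_universe]

  dir_a <- setNames(as.character(calls_a$direction), calls_a$feature_id)
  dir_b <- setNames(as.character(calls_b$direction), calls_b$feature_id)
  union_feats <- intersect(union(called_a, called_b), shared_universe)
  common <- intersect(intersect(called_a, called_b), shared_universe)
  common <- common[dir_a[common] == dir_b[common]]

  set_of <- function(f) {
    if (f %in% common) "common"
    else if (f %in% called_a) paste0(labels[1], "_only")
    else paste0(labels[2], "_only")
  }
  scatter <- tibble(feature_id = union_feats,
                    mean_a = unname(mean_a[union_feats]),
                    mean_b = unname(mean_b[union_feats]),
                    set = purrr::map_chr(union_feats, set_of))
  names(scatter)[2:3] <- paste0("mean_log2fc_", labels)

  r <- if (nrow(scatter) >= 3L) {
    cor(scatter[[2]], scatter[[3]])
  } else {
    NA_real_
  }

  slope_fit <- function(df) {
    if (nrow(df) < 3L) {
      return(tibble(slope = NA_real_, conf_low = NA_real_,
                    conf_high = NA_real_, n = nrow(df)))
    }
    fit <- lm(df[[3]] ~ df[[2]])
    # perfect fits (e.g. exactly proportional groups) are legitimate here
    ci <- suppressWarnings(confint(fit, level = 0.95))
    tibble(slope = unname(coef(fit)[2]),
           conf_low = ci[2, 1], conf_high = ci[2, 2], n = nrow(df))
  }
  slopes <- scatter %>%
    group_by(set = .data$set) %>%
    dplyr::group_modify(~ slope_fit(.x)) %>%
    ungroup()

  structure(list(scatter = scatter, pearson_r = r, slopes = slopes,
                 labels = labels),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat("Genotype-effect comparison (", x$labels[1], " vs ", x$labels[2], ")\n",
      sep = "")
  cat("  features in scatter:", nrow(x$scatter), "\n")
  cat("  Pearson r over union:", format(x$pearson_r, digits = 4), "\n")
  print(x$slopes)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.genotype_comparison <- function(x, ...) {
  tibble(n_features = nrow(x$scatter),
         n_common = sum(x$scatter$set == "common"),
         pearson_r = x$pearson_r)
}

#' @exportS3Method generics::tidy
tidy.genotype_comparison <- function(x, ...) x$slopes

#' Correlation of the two construct responses over the most variable genes
#'
#' Ranks features by their standard deviation across all samples, keeps the
#' `n_top` most variable (ties at the boundary broken by feature id), and for
#' each patient computes the Pearson correlation between the expression
#' vectors of that patient's two non-control constructs over those features.
#' Used to ask whether two paralogous constructs (e.g. NOTCH1 vs NOTCH2
#' intracellular domains) drive the same expression program.
#'
#' @param x Normalized feature matrix tibble covering all samples.
#' @param samples Sample sheet; each patient must carry the two `conditions`.
#' @param n_top Number of top-variance features to retain.
#' @param conditions Length-2 character vector naming the two constructs to
#'   correlate; defaults to the two non-`control` conditions in the sheet.
#' @return A tibble: `patient_id`, `pearson_r`, `n_features`.
#' @export
top_variable_correlation <- function(x, samples, n_top = 500L,
                                     conditions = NULL) {
  fm_validate(x)
  sheet_validate(samples)
  if (is.null(conditions)) {
    conditions <- setdiff(unique(samples$condition), "control")
  }
  if (length(conditions) != 2L) {
    abort("Exactly two construct conditions are required.")
  }
  m <- fm_matrix(x)
  check_scalar_number(n_top, "n_top", lower = 1, integerish = TRUE)
  if (n_top > nrow(m)) {
    abort(sprintf("`n_top` (%d) exceeds the number of features (%d).",
                  n_top, nrow(m)))
  }
  sds <- apply(m, 1L, sd)
  ord <- order(-sds, rownames(m))
  top <- rownames(m)[ord[seq_len(n_top)]]

  per_construct <- samples %>%
    filter(.data$condition %in% conditions,
           .data$sample_id %in% colnames(m))
  pairs <- per_construct %>%
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "condition",
                       values_from = "sample_id")
  bad <- pairs$patient_id[!complete.cases(pairs[, conditions])]
  if (length(bad)) {
    abort(sprintf("Patient(s) missing a construct sample: %s.",
                  paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    tibble(patient_id = as.character(pairs$patient_id[i]),
           pearson_r = cor(m[top, pairs[[conditions[1]]][i]],
                           m[top, pairs[[conditions[2]]][i]]),
           n_features = n_top)
  })
}
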