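#' Variance-stabilizing transform of peak counts
#'
#' Median-of-ratios size factors (geometric-mean reference over peaks with
#' all-positive counts) followed by `log2(count / size_factor + 1)`. A pure
#' depth-scaled replicate column maps to a near-identical column, which is
#' the property the downstream PCA and correlation steps rely on. If no peak
#' has all-positive counts the size factors fall back to relative library
#' sizes, with a warning.
#'
#' @param x Raw peak count tibble (`feature_id` + sample columns).
#' @return Tibble of the same shape with stabilized values; size factors are
#'   attached as attribute `"size_factors"`.
#' @export
vst_transform <- function(x) {
  fm_validate(x, require_nonneg = TRUE)
  m <- fm_matrix(x)
  if (ncol(m) < 2L) abort("VST needs at least 2 samples.")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    log_geo <- rowMeans(log(m[all_pos, , drop = FALSE]))
    sf <- apply(m[all_pos, , drop = FALSE], 2L,
                function(col) exp(median(log(col) - log_geo)))
  } else {
    warn("No peak has all-positive counts; falling back to library-size factors.")
    lib <- colSums(m)
    sf <- lib / geometric_mean(lib)
  }
  out <- log2(sweep(m, 2L, sf, "/") + 1)
  res <- fm_tibble(out)
  attr(res, "size_factors") <- tibble(sample_id = colnames(m),
                                      size_factor = unname(sf))
  res
}

#' Principal component analysis over samples
#'
#' PCA with samples as observations and peaks as variables (per-peak
#' centring, no scaling), the orientation in which patient identity shows up
#' in the leading components of paired cohorts and a condition-associated
#' component can appear further down the spectrum. Component signs are fixed
#' so the largest-magnitude peak loading of each component is positive.
#'
#' @param x Variance-stabilized peak tibble from [vst_transform()].
#' @return A `peak_pca` object: `scores` (tibble sample_id x PCs — the
#'   per-sample component values that get correlated against peaks),
#'   `loadings` (feature_id x PCs), `explained` (component, variance,
#'   explained_fraction).
#' @export
pca_over_samples <- function(x) {
  fm_validate(x)
  m <- fm_matrix(x)
  if (ncol(m) < 3L) abort("PCA over samples needs at least 3 samples.")
  tm <- t(m)
  if (sum(apply(tm, 2L, var)) <= 0) {
    abort("Constant matrix: zero total variance, PCA undefined.")
  }
  p <- prcomp(tm, center = TRUE, scale. = FALSE)
  # fix signs: largest-|loading| positive
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2L, flip, "*")
  p$x <- sweep(p$x, 2L, flip, "*")

  vars <- p$sdev^2
  explained <- tibble(component = seq_along(vars),
                      variance = vars,
                      explained_fraction = vars / sum(vars))
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(p$x)),
                             as_tibble(p$x))
  loadings <- dplyr::bind_cols(tibble(feature_id = rownames(p$rotation)),
                               as_tibble(p$rotation))
  structure(list(scores = scores, loadings = loadings, explained = explained),
            class = "peak_pca")
}

#' @export
print.peak_pca <- function(x, ...) {
  cat("PCA over", nrow(x$scores), "samples x", nrow(x$loadings), "peaks\n")
  print(head(x$explained, 6L))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.peak_pca <- function(x, ...) x$explained

#' Correlation of component scores with the condition contrast
#'
#' Reports, for every principal component, the Pearson correlation of its
#' sample scores with the control/treated indicator, alongside the explained
#' variance fraction. This is plumbing to guide the (explicit, user-made)
#' choice of which component carries the condition signal; in real cohorts
#' that choice is made by inspecting exactly this kind of table.
#'
#' @param pca A [pca_over_samples()] result.
#' @param samples Sample sheet covering the scored samples.
#' @return Tibble: `component`, `cor_condition`, `explained_fraction`,
#'   ordered by component.
#' @export
condition_component <- function(pca, samples) {
  stopifnot(inherits(pca, "peak_pca"))
  sheet_validate(samples)
  idx <- match(pca$scores$sample_id, samples$sample_id)
  if (anyNA(idx)) {
    abort("Sample sheet does not cover all scored samples.")
  }
  cond <- as.integer(samples$condition[idx] == "treated")
  pcs <- as.matrix(pca$scores[, -1, drop = FALSE])
  tibble(component = seq_len(ncol(pcs)),
         cor_condition = as.numeric(cor(pcs, cond)),
         explained_fraction = pca$explained$explained_fraction)
}

#' Select peaks correlated with a principal component
#'
#' For each peak, the Pearson correlation between its stabilized values
#' across samples and the chosen component's sample scores; two-sided
#' p-values from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Peaks with `p < alpha` are retained, in both correlation signs.
#' Zero-variance peaks (correlation undefined) are excluded with a message.
#'
#' @param x Variance-stabilized peak tibble.
#' @param pca A [pca_over_samples()] result on the same matrix.
#' @param component Component index to correlate against (chosen explicitly,
#'   e.g. via [condition_component()]).
#' @param alpha Retention threshold on the (unadjusted) p-value; the rule is
#'   deliberately per-peak `p < alpha`, set `adjust = "BH"` to switch to FDR.
#' @param peaks Optional tibble mapping `feature_id` to `chrom`, `start`,
#'   `end`; when absent, ids of the form `"chr:start-end"` are parsed so the
#'   downstream genomic filters can run.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Signature tibble: coordinates (when available), `feature_id`,
#'   `pearson_r`, `p_value`, `stage = "pc_correlated"`.
#' @export
select_pc_correlated_peaks <- function(x, pca, component, alpha = 0.05,
                                       peaks = NULL,
                                       adjust = c("none", "BH")) {
  fm_validate(x)
  stopifnot(inherits(pca, "peak_pca"))
  adjust <- arg_match(adjust)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  pcs <- as.matrix(pca$scores[, -1, drop = FALSE])
  check_scalar_number(component, "component", lower = 1, upper = ncol(pcs),
                      integerish = TRUE)
  m <- fm_matrix(x)
  n <- ncol(m)
  if (n < 4L) abort("Need at least 4 samples for the correlation p-value.")
  ord <- match(colnames(m), pca$scores$sample_id)
  if (anyNA(ord)) abort("PCA scores do not cover all matrix samples.")
  sc <- pcs[ord, component]

  keep <- apply(m, 1L, sd) > 0
  if (any(!keep)) {
    inform(sprintf("Excluding %d zero-variance peak(s) from the correlation filter.",
                   sum(!keep)))
  }
  mm <- m[keep, , drop = FALSE]
  r <- as.numeric(cor(t(mm), sc))
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  padj <- if (adjust == "BH") benjamini_hochberg(p) else p

  out <- tibble(feature_id = rownames(mm), pearson_r = r, p_value = p) %>%
    filter(padj < alpha) %>%
    mutate(stage = "pc_correlated")

  coords <- NULL
  if (!is.null(peaks)) {
    validate_intervals(peaks, arg = "peaks")
    if (!"feature_id" %in% names(peaks)) {
      abort("`peaks` needs a `feature_id` column.")
    }
    coords <- peaks %>% select("feature_id", "chrom", "start", "end")
  } else if (all(grepl("^[^:]+:\\d+-\\d+$", out$feature_id))) {
    coords <- tibble(feature_id = out$feature_id) %>%
      tidyr::extract("feature_id", c("chrom", "start", "end"),
                     "^([^:]+):(\\d+)-(\\d+)$", remove = FALSE,
                     convert = TRUE)
  }
  if (!is.null(coords)) {
    out <- out %>%
      left_join(coords, by = "feature_id") %>%
      select("chrom", "start", "end", "feature_id", "pearson_r",
             "p_value", "stage")
  }
  out
}

#' Remove peaks in inactive chromatin
#'
#' Retains signature peaks overlapping (by at least one base pair) an
#' interval of an active chromatin state. Chromosomes absent from the state
#' track are treated as inactive, with a message.
#'
#' @param signature Signature tibble with `chrom`, `start`, `end` columns.
#' @param states Chromatin-state tibble: `chrom`, `start`, `end`, `state`,
#'   and either a logical `active` column or an `active_states` vector here.
#' @param active_states Character vector of state labels considered active
#'   (required when `states` has no `active` column).
#' @param inactive_states Optional character vector of labels considered
#'   inactive; when given, every label must appear in one of the two sets and
#'   an unclassified label is an error. When omitted, labels not listed as
#'   active are inactive by exclusion.
#' @return Filtered signature tibble with `stage = "state_filtered"`.
#' @export
filter_by_chromatin_state <- function(signature, states, active_states = NULL,
                                      inactive_states = NULL) {
  validate_intervals(signature, arg = "signature")
  validate_intervals(states, arg = "states")
  if (!"state" %in% names(states)) abort("`states` needs a `state` column.")
  if (!"active" %in% names(states)) {
    if (is.null(active_states)) {
      abort("Provide `active_states` or an `active` column in `states`.")
    }
    if (!is.null(inactive_states)) {
      unknown <- setdiff(unique(states$state),
                         c(active_states, inactive_states))
      if (length(unknown)) {
        abort(sprintf("Unknown chromatin state label(s): %s.",
                      paste(unknown, collapse = ", ")))
      }
    }
    states$active <- states$state %in% active_states
  }
  if (any(is.na(states$active))) {
    bad <- unique(states$state[is.na(states$active)])
    abort(sprintf("State label(s) with unknown activity: %s.",
                  paste(bad, collapse = ", ")))
  }
  uncovered <- setdiff(unique(signature$chrom), unique(states$chrom))
  if (length(uncovered)) {
    inform(sprintf("Chromosome(s) not covered by the state track, treated inactive: %s.",
                   paste(uncovered, collapse = ", ")))
  }
  active_gr <- intervals_to_gr(states[states$active, , drop = FALSE])
  # disjoint seqlevels are expected (uncovered chromosomes count as inactive)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(intervals_to_gr(signature), active_gr)
  )
  out <- signature[hits > 0L, , drop = FALSE]
  out$stage <- "state_filtered"
  out
}

#' Annotate signature peaks to promoter-extended genes
#'
#' Extends every gene 5'-ward by `promoter_extension` base pairs (start for
#' `+` genes, end for `-` genes, clamped at zero) to take in its promoter,
#' then keeps peaks overlapping at least one extended gene. A peak
#' overlapping several genes is annotated to the one with the largest
#' overlap; ties break by gene id.
#'
#' @param signature Signature tibble with coordinates.
#' @param genes Gene-model tibble: `chrom`, `start`, `end`, `gene_id`,
#'   `strand` (`+`/`-`).
#' @param promoter_extension Upstream extension in base pairs.
#' @return Filtered signature tibble with `annotated_gene` and
#'   `stage = "gene_annotated"`.
#' @export
annotate_to_genes <- function(signature, genes, promoter_extension = 1500L) {
  validate_intervals(signature, arg = "signature")
  validate_intervals(genes, arg = "genes")
  if (!all(c("gene_id", "strand") %in% names(genes))) {
    abort("`genes` needs `gene_id` and `strand` columns.")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("Gene strands must be '+' or '-'.")
  }
  check_scalar_number(promoter_extension, "promoter_extension", lower = 0,
                      integerish = TRUE)
  ext <- genes %>%
    mutate(start = if_else(.data$strand == "+",
                           pmax(0, .data$start - promoter_extension),
                           .data$start),
           end = if_else(.data$strand == "-",
                         .data$end + promoter_extension,
                         .data$end))
  sig_gr <- intervals_to_gr(signature)
  gene_gr <- intervals_to_gr(ext)
  hits <- GenomicRanges::findOverlaps(sig_gr, gene_gr)
  if (!length(hits)) {
    out <- signature[0, , drop = FALSE]
    out$annotated_gene <- character(0)
    out$stage <- character(0)
    return(out)
  }
  ov <- GenomicRanges::pintersect(sig_gr[S4Vectors::queryHits(hits)],
                                  gene_gr[S4Vectors::subjectHits(hits)])
  assign_tbl <- tibble(peak = S4Vectors::queryHits(hits),
                       gene_id = ext$gene_id[S4Vectors::subjectHits(hits)],
                       overlap = GenomicRanges::width(ov)) %>%
    arrange(.data$peak, desc(.data$overlap), .data$gene_id) %>%
    distinct(.data$peak, .keep_all = TRUE)
  out <- signature[assign_tbl$peak, , drop = FALSE]
  out$annotated_gene <- assign_tbl$gene_id
  out$stage <- "gene_annotated"
  out
}
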