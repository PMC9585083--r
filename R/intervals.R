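# Interval tibbles use BED semantics throughout: 0-based, half-open
# [start, end). GRanges (1-based, closed) is the internal engine.

validate_intervals <- function(x, arg = caller_arg(x)) {
  needed <- c("chrom", "start", "end")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$end <= x$start)
  if (length(bad)) {
    abort(sprintf("`%s` has malformed interval(s) at row(s) %s (need 0 <= start < end).",
                  arg, paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(x)
}

intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_intervals <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Build consensus peaks across samples
#'
#' Merges the per-sample peak calls into one consensus set by base-pair
#' union: overlapping and book-ended intervals are collapsed. Each consensus
#' peak records its support, the number of distinct samples contributing at
#' least one overlapping base pair.
#'
#' @param peak_calls Tibble of per-sample peaks: `chrom`, `start`, `end`
#'   (0-based half-open), `sample_id`.
#' @return Consensus tibble: `chrom`, `start`, `end`, `support`, sorted by
#'   position.
#' @examples
#' calls <- tibble::tibble(chrom = "chr1",
#'                         start = c(100, 150), end = c(200, 250),
#'                         sample_id = c("s1", "s2"))
#' build_consensus(calls)  # one peak [100, 250) with support 2
#' @export
build_consensus <- function(peak_calls) {
  validate_intervals(peak_calls, arg = "peak_calls")
  if (!"sample_id" %in% names(peak_calls)) {
    abort("`peak_calls` needs a `sample_id` column.")
  }
  per_sample <- split(peak_calls, peak_calls$sample_id)
  per_sample_gr <- purrr::map(per_sample,
                              ~ GenomicRanges::reduce(intervals_to_gr(.x)))
  consensus <- GenomicRanges::reduce(
    do.call(c, unname(purrr::map(per_sample_gr, identity)))
  )
  consensus <- GenomicRanges::sort(consensus)
  support <- Reduce(`+`, purrr::map(per_sample_gr, function(gr) {
    as.integer(GenomicRanges::countOverlaps(consensus, gr) > 0L)
  }))
  out <- gr_to_intervals(consensus)
  out$support <- support
  out
}

#' Filter consensus peaks by sample support
#'
#' Retains consensus peaks present in (overlapped by peaks from) at least
#' `min_samples` samples. Order is preserved.
#'
#' @param consensus Tibble from [build_consensus()] with a `support` column.
#' @param min_samples Minimum number of contributing samples.
#' @return Filtered tibble.
#' @export
filter_by_support <- function(consensus, min_samples = 2L) {
  validate_intervals(consensus, arg = "consensus")
  if (!"support" %in% names(consensus)) {
    abort("`consensus` needs a `support` column (see build_consensus()).")
  }
  check_scalar_number(min_samples, "min_samples", lower = 1, integerish = TRUE)
  consensus %>% filter(.data$support >= min_samples)
}
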