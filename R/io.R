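# Readers/writers for the plain-text formats the pipeline exchanges.
# Matrices, sheets and cohort tables are TSV (readr); peaks and signal go
# through rtracklayer's BED/bedGraph import/export, converted to the
# package's 0-based half-open tibble convention.

#' Read / write a feature-by-sample matrix as TSV
#'
#' First column `feature_id`, one column per sample.
#' @param path File path.
#' @return A feature matrix tibble.
#' @export
read_feature_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  fm_validate(x)
  x
}

#' @rdname read_feature_matrix
#' @param x Feature matrix tibble.
#' @export
write_feature_matrix <- function(x, path) {
  fm_validate(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a sample sheet as TSV
#'
#' Columns `sample_id`, `patient_id`, `condition` and optionally `genotype`.
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  sheet_validate(x)
  x
}

#' @rdname read_sample_sheet
#' @param x Sample sheet tibble.
#' @export
write_sample_sheet <- function(x, path) {
  sheet_validate(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write peak intervals as BED
#'
#' Plain BED3 via rtracklayer; extra columns (e.g. `support`,
#' correlation statistics) are carried as additional tab-separated columns
#' after the first three.
#' @param path File path.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- gr_to_intervals(gr)
  extra <- as_tibble(as.data.frame(S4Vectors::mcols(gr)))
  if (ncol(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

#' @rdname read_bed
#' @param x Interval tibble (`chrom`, `start`, `end`, extra columns kept).
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  extra <- x[, setdiff(names(x), c("chrom", "start", "end")), drop = FALSE]
  out <- x[, c("chrom", "start", "end")]
  if (ncol(extra)) out <- dplyr::bind_cols(out, extra)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a signal track as bedGraph
#'
#' @param path File path.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- gr_to_intervals(gr)
  out$value <- S4Vectors::mcols(gr)$score
  out
}

#' @rdname read_bedgraph
#' @param x Signal tibble (`chrom`, `start`, `end`, `value`).
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x)
  gr <- intervals_to_gr(x)
  S4Vectors::mcols(gr)$score <- x$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a cohort table as TSV
#'
#' Columns `patient_id`, `hes1`, `hes2`, `hey1`, `hey2`, `ciita`,
#' `notch1_mutated`, `time`, `event`.
#' @param path File path.
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
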