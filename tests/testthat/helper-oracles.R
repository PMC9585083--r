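# Independent brute-force oracles. These deliberately re-derive each result
# with the most literal method available (per-feature loops, dense per-bp
# vectors, textbook formulas) and stay independent of the package internals.

# Literal re-evaluation of a consistency criterion for one feature.
oracle_direction <- function(fc, fc_threshold, min_fraction,
                             require_all_same_sign, require_mean_threshold) {
  n <- length(fc)
  need <- ceiling(min_fraction * n)
  up <- if (require_mean_threshold) mean(fc) > fc_threshold
        else sum(fc > fc_threshold) >= need
  dn <- if (require_mean_threshold) mean(fc) < -fc_threshold
        else sum(fc < -fc_threshold) >= need
  if (require_all_same_sign) {
    up <- up && all(fc > 0)
    dn <- dn && all(fc < 0)
  }
  if (up && dn) return("not_called")
  if (up) return("up")
  if (dn) return("down")
  "not_called"
}

oracle_calls <- function(fc_matrix, criterion) {
  vapply(seq_len(nrow(fc_matrix)), function(i) {
    oracle_direction(fc_matrix[i, ],
                     criterion$fc_threshold, criterion$min_fraction,
                     criterion$require_all_same_sign,
                     criterion$require_mean_threshold)
  }, character(1))
}

# Dense per-base-pair interval oracle on a small genome (one chromosome).
# Returns a logical occupancy vector over [0, genome_len).
oracle_occupancy <- function(starts, ends, genome_len) {
  occ <- logical(genome_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) occ[(starts[i] + 1):ends[i]] <- TRUE
  }
  occ
}

# Maximal runs of TRUE in an occupancy vector, as 0-based half-open intervals.
oracle_runs <- function(occ) {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Number of samples whose peaks overlap >= 1 bp of [start, end).
oracle_support <- function(start, end, per_sample_occ) {
  sum(vapply(per_sample_occ,
             function(occ) any(occ[(start + 1):end]), logical(1)))
}

random_fc_table <- function(n_features, n_pairs, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_features * n_pairs, 0, 1), n_features)
    # salt in borderline and extreme values so every branch is exercised
    m[sample(length(m), n_features %/% 4)] <-
      sample(c(-0.5, 0.5, 0, 2, -2), n_features %/% 4, replace = TRUE)
    dimnames(m) <- list(sprintf("f%05d", seq_len(n_features)),
                        sprintf("P%02d", seq_len(n_pairs)))
    m
  })
}

fc_matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                   tibble::as_tibble(m))
}

# Random fuzzed interval set on one chromosome.
random_intervals <- function(n, genome_len, max_width = 400L) {
  start <- sample.int(genome_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = "chrT", start = start,
                 end = pmin(start + width, genome_len))
}

make_paired_sheet <- function(n_patients) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  tibble::tibble(
    sample_id = as.vector(rbind(paste0(pid, "_EV"), paste0(pid, "_N1"))),
    patient_id = rep(pid, each = 2),
    condition = rep(c("control", "treated"), n_patients)
  )
}
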