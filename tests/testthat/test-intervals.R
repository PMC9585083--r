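test_that("consensus merging follows base-pair union semantics", {
  one <- tibble::tibble(chrom = "chr1", start = c(100, 300), end = c(200, 400),
                        sample_id = "s1")
  cons <- build_consensus(one)
  expect_equal(cons$start, c(100, 300))
  expect_equal(cons$support, c(1L, 1L))

  two <- dplyr::bind_rows(one,
    tibble::tibble(chrom = "chr1", start = 150, end = 250, sample_id = "s2"))
  cons2 <- build_consensus(two)
  expect_equal(cons2[cons2$start == 100, ]$end, 250)
  expect_equal(cons2[cons2$start == 100, ]$support, 2L)

  # book-ended intervals merge (per-bp union)
  adj <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                        sample_id = c("s1", "s2"))
  cons3 <- build_consensus(adj)
  expect_equal(nrow(cons3), 1L)
  expect_equal(c(cons3$start, cons3$end, cons3$support), c(0, 200, 2))

  expect_error(build_consensus(
    tibble::tibble(chrom = "chr1", start = 10, end = 10, sample_id = "s1")),
    "row")
})

test_that("consensus and support match the dense per-bp oracle on fuzzed input", {
  genome_len <- 10000L
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n_samples <- sample(2:4, 1)
      calls <- purrr::map_dfr(seq_len(n_samples), function(s) {
        random_intervals(sample(5:25, 1), genome_len) |>
          dplyr::mutate(sample_id = paste0("s", s))
      })
    })
    cons <- build_consensus(calls)
    per_sample_occ <- lapply(split(calls, calls$sample_id), function(df) {
      oracle_occupancy(df$start, df$end, genome_len)
    })
    union_occ <- Reduce(`|`, per_sample_occ)
    runs <- oracle_runs(union_occ)
    expect_equal(cons$start, runs$start)
    expect_equal(cons$end, runs$end)
    expect_equal(cons$support,
                 vapply(seq_len(nrow(runs)), function(i) {
                   oracle_support(runs$start[i], runs$end[i], per_sample_occ)
                 }, integer(1)))
  }
})

test_that("support filtering counts exactly", {
  cons <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200),
                         end = c(50, 150, 250), support = c(1L, 2L, 3L))
  expect_equal(filter_by_support(cons, 1), cons)
  expect_equal(nrow(filter_by_support(cons, 2)), 2L)
  withr::with_seed(5, {
    fuzz <- tibble::tibble(chrom = "chr1",
                           start = seq(0, 990, 10), end = seq(5, 995, 10),
                           support = sample(1:6, 100, replace = TRUE))
  })
  for (thr in 1:6) {
    expect_equal(nrow(filter_by_support(fuzz, thr)), sum(fuzz$support >= thr))
  }
})

test_that("chromatin-state filtering respects half-open overlap semantics", {
  sig <- tibble::tibble(chrom = "chr1", start = 100, end = 200,
                        feature_id = "p1", pearson_r = 0.9, p_value = 0.01,
                        stage = "pc_correlated")
  retained <- filter_by_chromatin_state(
    sig, tibble::tibble(chrom = "chr1", start = 199, end = 300,
                        state = "active"), active_states = "active")
  expect_equal(nrow(retained), 1L)          # 1 bp overlap
  expect_equal(retained$stage, "state_filtered")

  removed <- filter_by_chromatin_state(
    sig, tibble::tibble(chrom = "chr1", start = 200, end = 300,
                        state = "active"), active_states = "active")
  expect_equal(nrow(removed), 0L)           # book-ended, no shared bp

  all_active <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                               state = "active")
  expect_equal(nrow(filter_by_chromatin_state(sig, all_active,
                                              active_states = "active")), 1L)

  # uncovered chromosome treated inactive, with a message
  sig2 <- dplyr::mutate(sig, chrom = "chrUn")
  expect_message(
    out <- filter_by_chromatin_state(sig2, all_active, active_states = "active"),
    "chrUn")
  expect_equal(nrow(out), 0L)

  expect_error(filter_by_chromatin_state(
    sig, tibble::tibble(chrom = "chr1", start = 0, end = 10, state = "mystery"),
    active_states = "active", inactive_states = "quiescent"),
    "mystery")
})

test_that("gene annotation extends promoters strand-awarely", {
  genes <- tibble::tibble(chrom = "chr1", start = 5000, end = 9000,
                          gene_id = "GENE1", strand = "+")
  sig <- tibble::tibble(chrom = "chr1", start = c(3600, 3400, 6000),
                        end = c(3700, 3490, 6100),
                        feature_id = c("pA", "pB", "pC"),
                        stage = "state_filtered")
  out <- annotate_to_genes(sig, genes, promoter_extension = 1500)
  # extended start is 3500: pA (3600) in the promoter window, pB out, pC in body
  expect_setequal(out$feature_id, c("pA", "pC"))
  expect_true(all(out$annotated_gene == "GENE1"))
  expect_true(all(out$stage == "gene_annotated"))

  # minus-strand promoter extends rightward
  genes_m <- tibble::tibble(chrom = "chr1", start = 5000, end = 9000,
                            gene_id = "GENE2", strand = "-")
  sigm <- tibble::tibble(chrom = "chr1", start = 10000, end = 10100,
                         feature_id = "pD", stage = "state_filtered")
  expect_equal(nrow(annotate_to_genes(sigm, genes_m, 1500)), 1L)
  expect_equal(nrow(annotate_to_genes(sigm, genes_m, 500)), 0L)

  # largest overlap wins; ties break by gene id
  genes2 <- tibble::tibble(chrom = "chr1", start = c(0, 120), end = c(150, 400),
                           gene_id = c("B_GENE", "A_GENE"),
                           strand = c("+", "+"))
  sig2 <- tibble::tibble(chrom = "chr1", start = 100, end = 300,
                         feature_id = "pE", stage = "state_filtered")
  out2 <- annotate_to_genes(sig2, genes2, promoter_extension = 0)
  expect_equal(out2$annotated_gene, "A_GENE")  # overlap 180 vs 50
  tie_genes <- tibble::tibble(chrom = "chr1", start = c(100, 100),
                              end = c(300, 300),
                              gene_id = c("ZZ", "AA"), strand = c("+", "+"))
  expect_equal(annotate_to_genes(sig2, tie_genes, 0)$annotated_gene, "AA")
})

test_that("annotation matches a brute-force all-pairs oracle on fuzzed input", {
  genome_len <- 20000L
  for (seed in 1:6) {
    withr::with_seed(seed, {
      sig <- random_intervals(15, genome_len) |>
        dplyr::mutate(feature_id = sprintf("p%02d", dplyr::row_number()),
                      stage = "state_filtered")
      genes <- random_intervals(10, genome_len) |>
        dplyr::mutate(gene_id = sprintf("g%02d", dplyr::row_number()),
                      strand = sample(c("+", "-"), 10, replace = TRUE))
    })
    ext <- 1000L
    out <- annotate_to_genes(sig, genes, promoter_extension = ext)
    # oracle: explicit O(n*m) overlap of promoter-extended genes
    g_start <- ifelse(genes$strand == "+", pmax(0, genes$start - ext), genes$start)
    g_end <- ifelse(genes$strand == "-", genes$end + ext, genes$end)
    kept <- character(0); annot <- character(0)
    for (i in seq_len(nrow(sig))) {
      ov <- pmin(sig$end[i], g_end) - pmax(sig$start[i], g_start)
      hit <- which(ov > 0)
      if (length(hit)) {
        kept <- c(kept, sig$feature_id[i])
        best <- hit[order(-ov[hit], genes$gene_id[hit])][1]
        annot <- c(annot, genes$gene_id[best])
      }
    }
    expect_setequal(out$feature_id, kept)
    expect_equal(out$annotated_gene[match(kept, out$feature_id)], annot)
  }
})
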