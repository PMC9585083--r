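# End-to-end demonstration pipeline over synthetic data: simulate -> paired
# DE calling -> chromatin signature cascade -> survival stratification, with
# a run manifest recording per-stage record counts (the analysis's
# "peaks surviving each filter" bookkeeping) and output digests.

pipeline_schema <- list(
  top = c("seed", "out_dir", "stages", "simulate", "de_call",
          "chip_signature", "stratify"),
  simulate = c("rnaseq", "chip", "cohort"),
  rnaseq = c("n_patients", "n_features", "frac_affected", "effect_log2fc_mean",
             "effect_log2fc_sd", "patient_effect_sd", "dispersion",
             "lib_size_range", "baseline_log2_range"),
  chip = c("n_patients", "n_features", "pc_effect_frac", "effect_log2fc_mean",
           "effect_log2fc_sd", "patient_effect_sd", "dispersion",
           "lib_size_range", "baseline_log2_range", "n_chroms"),
  cohort = c("n_patients", "baseline_hazard", "hazard_ratio_risk_group",
             "censoring_rate", "mutation_odds_ratio_low_ciita",
             "ciita_threshold", "baseline_mutation_prob"),
  de_call = c("criterion", "fc_threshold", "pseudocount", "normalization"),
  chip_signature = c("component", "alpha", "min_support", "promoter_extension"),
  stratify = c("notch_threshold", "ciita_threshold")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s) in %s: %s.",
                  where, paste(unknown, collapse = ", ")),
          class = "notchsig_config_error")
  }
  invisible(x)
}

config_error <- function(msg) abort(msg, class = "notchsig_config_error")

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order on freshly simulated
#' data: `simulate` (paired RNA counts, peak experiment, survival cohort),
#' `de_call` (normalization, per-pair fold changes, consistency calling),
#' `chip_signature` (consensus peaks, support filter, VST, PCA, component
#' correlation, chromatin-state and gene filters, subtracted signal) and
#' `stratify` (four-group NOTCH/CIITA stratification, log-rank, Fisher
#' mutation enrichment). Every stage's record counts land in the returned
#' manifest; identical config plus seed gives identical scientific outputs.
#'
#' @param config A configuration list or the path to a YAML file. Unknown
#'   keys anywhere in the configuration are rejected before any computation.
#' @param out_dir Optional output directory (overrides the config value);
#'   when set, stage outputs (TSV/BED/bedGraph) and `manifest.json` are
#'   written there.
#' @param seed Optional integer overriding the config seed; stage generators
#'   derive their seeds from it.
#' @return The run manifest (list) invisibly: tool version, resolved
#'   configuration, per-stage `counts`, output file digests and wall
#'   timestamps.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(sprintf("Config file not found: %s.", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("`config` must be a list or a YAML path.")
  check_keys(config, pipeline_schema$top, "top level")
  sim_cfg <- config$simulate %||% list()
  check_keys(sim_cfg, pipeline_schema$simulate, "simulate")
  check_keys(sim_cfg$rnaseq %||% list(), pipeline_schema$rnaseq, "simulate$rnaseq")
  check_keys(sim_cfg$chip %||% list(), pipeline_schema$chip, "simulate$chip")
  check_keys(sim_cfg$cohort %||% list(), pipeline_schema$cohort, "simulate$cohort")
  check_keys(config$de_call %||% list(), pipeline_schema$de_call, "de_call")
  check_keys(config$chip_signature %||% list(), pipeline_schema$chip_signature,
             "chip_signature")
  check_keys(config$stratify %||% list(), pipeline_schema$stratify, "stratify")

  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  stages <- config$stages %||% c("simulate", "de_call", "chip_signature", "stratify")
  known_stages <- c("simulate", "de_call", "chip_signature", "stratify")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) {
    config_error(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(tool = "notchsig",
                   version = as.character(packageVersion("notchsig")),
                   started = format(Sys.time(), tz = "UTC"),
                   seed = seed,
                   stages = stages,
                   config = config,
                   counts = list(),
                   outputs = list())
  written <- character(0)
  emit <- function(x, name, writer) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      writer(x, path)
      written <<- c(written, path)
    }
  }

  needs_sim <- any(c("de_call", "chip_signature", "stratify", "simulate") %in% stages)
  if (!needs_sim) config_error("No stages requested.")

  # ---- simulate ------------------------------------------------------------
  rna_args <- sim_cfg$rnaseq %||% list()
  rna_cfg <- do.call(sim_config, c(rna_args, list(seed = seed)))
  chip_args <- sim_cfg$chip %||% list()
  pc_frac <- chip_args$pc_effect_frac %||% 0.02
  chip_args$pc_effect_frac <- NULL
  n_chroms <- chip_args$n_chroms %||% 4L
  chip_args$n_chroms <- NULL
  chip_defaults <- list(n_patients = 5L, n_features = 2000L,
                        effect_log2fc_mean = 1.5, patient_effect_sd = 0.5,
                        dispersion = 50)
  chip_args <- utils::modifyList(chip_defaults, chip_args)
  chip_cfg <- do.call(sim_config, c(chip_args, list(seed = seed + 1L)))
  cohort_cfg <- do.call(survival_sim_config,
                        c(sim_cfg$cohort %||% list(), list(seed = seed + 2L)))

  rna <- NULL; chip <- NULL; cohort <- NULL
  if (any(c("simulate", "de_call") %in% stages)) {
    rna <- simulate_paired_counts(rna_cfg)
    manifest$counts$rnaseq_genes <- nrow(rna$counts)
    manifest$counts$rnaseq_samples <- nrow(rna$samples)
    emit(rna$counts, "rnaseq_counts.tsv", write_feature_matrix)
    emit(rna$samples, "rnaseq_samples.tsv", write_sample_sheet)
    emit(rna$truth$features, "rnaseq_truth.tsv",
         function(x, p) readr::write_tsv(x, p))
  }
  if (any(c("simulate", "chip_signature") %in% stages)) {
    chip <- simulate_peak_experiment(chip_cfg, pc_effect_frac = pc_frac,
                                     n_chroms = n_chroms)
    manifest$counts$chip_peaks_simulated <- nrow(chip$peaks)
    manifest$counts$chip_samples <- nrow(chip$samples)
    emit(chip$counts, "chip_counts.tsv", write_feature_matrix)
    emit(chip$samples, "chip_samples.tsv", write_sample_sheet)
  }
  if (any(c("simulate", "stratify") %in% stages)) {
    cohort <- simulate_cohort(cohort_cfg)
    manifest$counts$cohort_patients <- nrow(cohort)
    manifest$counts$cohort_events <- sum(cohort$event)
    emit(cohort, "cohort.tsv", function(x, p) readr::write_tsv(x, p))
  }

  # ---- de_call -------------------------------------------------------------
  if ("de_call" %in% stages) {
    de_cfg <- config$de_call %||% list()
    norm <- normalize_counts(rna$counts,
                             method = de_cfg$normalization %||% "quantile+tmm")
    fc <- pairwise_log2fc(norm, rna$samples,
                          pseudocount = de_cfg$pseudocount %||% 1.0)
    crit <- de_criterion(de_cfg$criterion %||% "standard",
                         fc_threshold = de_cfg$fc_threshold %||% 0.5)
    calls <- call_consistency(fc, crit)
    manifest$counts$de_pairs <- ncol(fc) - 1L
    manifest$counts$de_called <- sum(calls$direction != "not_called")
    manifest$counts$de_up <- sum(calls$direction == "up")
    manifest$counts$de_down <- sum(calls$direction == "down")
    manifest$counts$de_conflicts <- sum(calls$conflict)
    emit(fc, "fold_changes.tsv", write_feature_matrix)
    emit(calls, "de_calls.tsv", function(x, p) readr::write_tsv(x, p))
  }

  # ---- chip_signature ------------------------------------------------------
  if ("chip_signature" %in% stages) {
    cs_cfg <- config$chip_signature %||% list()
    consensus <- build_consensus(chip$peak_calls)
    supported <- filter_by_support(consensus,
                                   min_samples = cs_cfg$min_support %||% 2L)
    keep_ids <- sprintf("%s:%d-%d", supported$chrom, supported$start,
                        supported$end)
    counts_kept <- chip$counts %>% filter(.data$feature_id %in% keep_ids)
    vst <- vst_transform(counts_kept)
    pca <- pca_over_samples(vst)
    comp_setting <- cs_cfg$component %||% "auto"
    comp_scan <- condition_component(pca, chip$samples)
    component <- if (identical(comp_setting, "auto")) {
      comp_scan$component[which.max(abs(comp_scan$cor_condition))]
    } else {
      as.integer(comp_setting)
    }
    sig <- select_pc_correlated_peaks(vst, pca, component,
                                      alpha = cs_cfg$alpha %||% 0.05)
    sig_state <- filter_by_chromatin_state(sig, chip$states)
    sig_gene <- annotate_to_genes(sig_state, chip$genes,
                                  promoter_extension =
                                    cs_cfg$promoter_extension %||% 1500L)
    subtracted <- paired_subtracted_signal(chip$signal, chip$samples)

    manifest$counts$chip_consensus_peaks <- nrow(consensus)
    manifest$counts$chip_supported_peaks <- nrow(supported)
    manifest$counts$chip_component <- as.integer(component)
    manifest$counts$chip_pc_correlated <- nrow(sig)
    manifest$counts$chip_state_filtered <- nrow(sig_state)
    manifest$counts$chip_gene_annotated <- nrow(sig_gene)
    manifest$counts$chip_subtracted_runs <- nrow(subtracted)
    emit(consensus, "consensus_peaks.bed", write_bed)
    emit(sig_gene, "signature_peaks.tsv", function(x, p) readr::write_tsv(x, p))
    emit(dplyr::bind_cols(tibble(component = comp_scan$component),
                          comp_scan[-1]),
         "pca_components.tsv", function(x, p) readr::write_tsv(x, p))
    emit(subtracted, "subtracted_signal.bedGraph", write_bedgraph)
  }

  # ---- stratify ------------------------------------------------------------
  if ("stratify" %in% stages) {
    st_cfg <- config$stratify %||% list()
    strat <- stratify_four_groups(cohort,
                                  notch_threshold = st_cfg$notch_threshold %||% "median",
                                  ciita_threshold = st_cfg$ciita_threshold %||% "median")
    lr <- logrank_test(strat, group = "four_group")
    km <- kaplan_meier(strat, group = "four_group")
    mut_tab <- table(factor(strat$ciita_group, levels = c("low", "high")),
                     factor(strat$notch1_mutated, levels = c(1, 0)))
    fish <- fisher_enrichment(mut_tab[1, 1], mut_tab[1, 2],
                              mut_tab[2, 1], mut_tab[2, 2])
    manifest$counts$strata_sizes <- as.list(table(strat$four_group))
    manifest$counts$logrank_df <- lr$df
    manifest$results <- list(logrank_statistic = lr$statistic,
                             logrank_p = lr$p_value,
                             fisher_odds_ratio = fish$odds_ratio,
                             fisher_p = fish$p_value)
    emit(strat, "stratified_cohort.tsv", function(x, p) readr::write_tsv(x, p))
    emit(tidy(km), "km_curves.tsv", function(x, p) readr::write_tsv(x, p))
  }

  if (!is.null(out_dir)) {
    manifest$outputs <- as.list(tools::md5sum(written))
    names(manifest$outputs) <- basename(written)
  }
  manifest$finished <- format(Sys.time(), tz = "UTC")
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(manifest)
}
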