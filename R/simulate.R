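#' Configuration for the paired count simulator
#'
#' Collects the knobs of the generative model used by
#' [simulate_paired_counts()] and [simulate_peak_experiment()]. The model is
#' additive on the log2 scale: each feature has a baseline log2 mean, each
#' feature x patient combination an offset (this is what makes the leading
#' principal components of real paired cohorts patient-specific), and planted
#' features carry a condition effect applied identically to every patient
#' pair. Means are exponentiated, multiplied by a per-sample library-size
#' factor, and counts drawn negative-binomial.
#'
#' @param n_patients Number of patients; each contributes one control and one
#'   treated sample.
#' @param n_features Number of features (genes or peaks).
#' @param frac_affected Fraction of features carrying a planted condition
#'   effect; `frac_affected * n_features` must round to a whole number of
#'   features.
#' @param effect_log2fc_mean Mean absolute planted effect, log2 units. Signs
#'   are drawn +/- with equal probability per feature.
#' @param effect_log2fc_sd Spread of the absolute planted effect across
#'   features (log2 units); `0` plants the same magnitude everywhere.
#' @param patient_effect_sd Standard deviation of the per-feature, per-patient
#'   baseline offsets (log2 units). Set large relative to the technical noise
#'   so patient identity dominates the variance structure, as observed in
#'   paired primary cohorts.
#' @param dispersion Negative-binomial shape ("size"); counts have
#'   variance `mu + mu^2 / dispersion`. `Inf` gives Poisson counts.
#' @param lib_size_range Length-2 positive range; per-sample library-size
#'   factors are drawn log-uniform within it.
#' @param baseline_log2_range Length-2 range of per-feature baseline log2
#'   means (counts scale as `2^baseline`).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 6L,
                       n_features = 2000L,
                       frac_affected = 0.05,
                       effect_log2fc_mean = 1.0,
                       effect_log2fc_sd = 0,
                       patient_effect_sd = 0.5,
                       dispersion = 10,
                       lib_size_range = c(0.8, 1.25),
                       baseline_log2_range = c(6, 10),
                       seed = 1L) {
  check_scalar_number(n_patients, "n_patients", lower = 2, integerish = TRUE)
  check_scalar_number(n_features, "n_features", lower = 1, integerish = TRUE)
  check_scalar_number(frac_affected, "frac_affected", lower = 0, upper = 1)
  n_affected <- frac_affected * n_features
  if (abs(n_affected - round(n_affected)) > 1e-8) {
    abort("`frac_affected * n_features` must be a whole number of features.")
  }
  check_scalar_number(effect_log2fc_mean, "effect_log2fc_mean")
  check_scalar_number(effect_log2fc_sd, "effect_log2fc_sd", lower = 0)
  check_scalar_number(patient_effect_sd, "patient_effect_sd", lower = 0)
  if (!(is.numeric(dispersion) && length(dispersion) == 1L && dispersion > 0)) {
    abort("`dispersion` must be a single positive number (Inf allowed).")
  }
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[2] < lib_size_range[1]) {
    abort("`lib_size_range` must be an increasing pair of positive numbers.")
  }
  if (length(baseline_log2_range) != 2L ||
      baseline_log2_range[2] < baseline_log2_range[1]) {
    abort("`baseline_log2_range` must be an increasing pair of numbers.")
  }
  check_scalar_number(seed, "seed", integerish = TRUE)
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 frac_affected = frac_affected,
                 effect_log2fc_mean = effect_log2fc_mean,
                 effect_log2fc_sd = effect_log2fc_sd,
                 patient_effect_sd = patient_effect_sd,
                 dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 baseline_log2_range = baseline_log2_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rnbinom_mu <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, lambda = mu) else rnbinom(n, mu = mu, size = size)
}

sim_draw_core <- function(config, feature_ids, genotypes) {
  n_pat <- config$n_patients
  patient_ids <- sprintf("P%02d", seq_len(n_pat))
  samples <- tibble(
    sample_id = as.vector(rbind(paste0(patient_ids, "_EV"),
                                paste0(patient_ids, "_N1"))),
    patient_id = rep(patient_ids, each = 2L),
    condition = rep(c("control", "treated"), n_pat),
    genotype = rep(genotypes, each = 2L)
  )

  n_feat <- config$n_features
  baseline <- runif(n_feat, config$baseline_log2_range[1], config$baseline_log2_range[2])
  offsets <- matrix(rnorm(n_feat * n_pat, 0, config$patient_effect_sd),
                    nrow = n_feat, dimnames = list(feature_ids, patient_ids))

  n_aff <- as.integer(round(config$frac_affected * n_feat))
  affected_idx <- if (n_aff > 0) sort(sample.int(n_feat, n_aff)) else integer(0)
  true_lfc <- numeric(n_feat)
  if (n_aff > 0) {
    magnitude <- config$effect_log2fc_mean +
      rnorm(n_aff, 0, config$effect_log2fc_sd)
    sign <- sample(c(-1, 1), n_aff, replace = TRUE)
    true_lfc[affected_idx] <- sign * magnitude
  }

  lib <- exp(runif(2L * n_pat, log(config$lib_size_range[1]),
                   log(config$lib_size_range[2])))
  cond_ind <- as.integer(samples$condition == "treated")
  pat_idx <- match(samples$patient_id, patient_ids)

  counts <- matrix(0L, nrow = n_feat, ncol = 2L * n_pat,
                   dimnames = list(feature_ids, samples$sample_id))
  for (s in seq_len(2L * n_pat)) {
    mu <- lib[s] * 2^(baseline + offsets[, pat_idx[s]] + cond_ind[s] * true_lfc)
    counts[, s] <- rnbinom_mu(n_feat, mu, config$dispersion)
  }

  truth <- list(
    features = tibble(feature_id = feature_ids,
                      baseline_log2 = baseline,
                      true_log2fc = true_lfc,
                      affected = seq_len(n_feat) %in% affected_idx),
    patient_offsets = fm_tibble(offsets),
    lib_sizes = tibble(sample_id = samples$sample_id, lib_size = lib)
  )
  class(truth) <- "synthetic_truth"
  list(counts = fm_tibble(counts), samples = samples, truth = truth)
}

#' Simulate a paired isogenic count experiment with planted truth
#'
#' Emits a raw count matrix for `2 * n_patients` samples (one empty-vector
#' control and one construct-transduced sample per patient), the matching
#' sample sheet, and the planted ground truth. Genotypes alternate between
#' `tri12` and `del13q` so genotype-stratified analyses can be exercised.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (feature-by-sample tibble), `samples`
#'   (sample sheet tibble: sample_id, patient_id, condition, genotype) and
#'   `truth` (planted effects, patient offsets, library sizes).
#' @examples
#' sim <- simulate_paired_counts(sim_config(n_patients = 3, n_features = 50,
#'                                          frac_affected = 0.1, seed = 7))
#' dplyr::filter(sim$truth$features, affected)
#' @export
simulate_paired_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  feature_ids <- sprintf("gene%05d", seq_len(config$n_features))
  genotypes <- rep(c("tri12", "del13q"), length.out = config$n_patients)
  withr::with_seed(config$seed, sim_draw_core(config, feature_ids, genotypes))
}

#' Simulate an H3K27ac-style peak experiment
#'
#' Lays out `n_features` non-overlapping peaks on a small synthetic genome,
#' draws per-peak counts from the paired generative model (patient-dominant
#' variance plus a consistent same-sign condition shift on the planted
#' peaks), and derives the artefacts a ChIP-seq signature analysis consumes:
#' per-sample peak calls (presence is Bernoulli with probability increasing
#' in that sample's abundance, so the at-least-two-samples filter is
#' non-trivial), per-sample rectangular signal tracks consistent with the
#' counts, a chromatin-state segmentation and strand-aware gene models
#' covering the genome.
#'
#' @param config A [sim_config()]; `frac_affected` is ignored in favour of
#'   `pc_effect_frac`.
#' @param pc_effect_frac Fraction of peaks carrying the planted condition
#'   effect (the component-forming peaks).
#' @param n_chroms Number of synthetic chromosomes the peaks are spread over.
#' @return A list with `peaks` (consensus universe: chrom/start/end/feature_id),
#'   `peak_calls` (per-sample BED-like tibble with `sample_id`), `signal`
#'   (per-sample bedGraph-like tibble), `counts`, `samples`, `truth`,
#'   `states` (chromatin-state segmentation with an `active` flag),
#'   `genes` (BED6-like gene models) and `chrom_sizes`.
#' @export
simulate_peak_experiment <- function(config = sim_config(n_patients = 5L,
                                                         n_features = 2000L,
                                                         effect_log2fc_mean = 1.5,
                                                         patient_effect_sd = 0.5,
                                                         dispersion = 50),
                                     pc_effect_frac = 0.02,
                                     n_chroms = 4L) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar_number(pc_effect_frac, "pc_effect_frac", lower = 0, upper = 1)
  if (config$patient_effect_sd <= 0) {
    abort("`patient_effect_sd` must be > 0: patient variance must dominate the condition effect.")
  }
  config$frac_affected <- pc_effect_frac

  withr::with_seed(config$seed, {
    n_feat <- config$n_features
    # peak layout: widths 300-800 bp, gaps 500-3000 bp, round-robin chroms
    chroms <- sprintf("chr%d", seq_len(n_chroms))
    chrom_of <- rep(chroms, length.out = n_feat)
    width <- sample(300:800, n_feat, replace = TRUE)
    gap <- sample(500:3000, n_feat, replace = TRUE)
    start <- integer(n_feat)
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      start[idx] <- cumsum(c(1000L, (width[idx] + gap[idx])[-length(idx)]))
    }
    peaks <- tibble(chrom = chrom_of, start = start, end = start + width) %>%
      mutate(feature_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)) %>%
      arrange(.data$chrom, .data$start)
    chrom_sizes <- peaks %>%
      group_by(chrom = .data$chrom) %>%
      summarise(size = max(.data$end) + 5000L, .groups = "drop")

    genotypes <- rep(c("tri12", "del13q"), length.out = config$n_patients)
    core <- sim_draw_core(config, peaks$feature_id, genotypes)

    cnt <- fm_matrix(core$counts)
    # presence: Bernoulli, probability rising with abundance, capped at 0.97
    med <- median(cnt)
    presence_prob <- cnt / (cnt + max(med, 1))
    presence_prob <- pmin(0.97, pmax(0.05, presence_prob))
    present <- matrix(rbinom(length(presence_prob), 1L, presence_prob) == 1L,
                      nrow = nrow(cnt), dimnames = dimnames(cnt))

    peak_calls <- purrr::map_dfr(colnames(cnt), function(s) {
      peaks[present[, s], c("chrom", "start", "end")] %>%
        mutate(sample_id = s)
    })

    signal <- purrr::map_dfr(colnames(cnt), function(s) {
      peaks %>%
        select("chrom", "start", "end") %>%
        mutate(value = cnt[, s] / (.data$end - .data$start), sample_id = s) %>%
        filter(.data$value > 0)
    })

    # chromatin states: tile each chromosome in 5 kb segments, ~60% active
    states <- purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
      brk <- seq(0L, chrom_sizes$size[i], by = 5000L)
      if (brk[length(brk)] < chrom_sizes$size[i]) brk <- c(brk, chrom_sizes$size[i])
      tibble(chrom = chrom_sizes$chrom[i],
             start = brk[-length(brk)], end = brk[-1]) %>%
        mutate(state = sample(c("active_enhancer", "active_promoter",
                                "heterochromatin", "quiescent"),
                              n(), replace = TRUE, prob = c(0.35, 0.25, 0.2, 0.2)))
    }) %>%
      mutate(active = .data$state %in% c("active_enhancer", "active_promoter"))

    # gene models: one gene spanning every other peak neighbourhood
    gene_src <- peaks %>% filter(row_number() %% 2L == 1L)
    genes <- gene_src %>%
      transmute(chrom = .data$chrom,
                start = pmax(0L, .data$start - sample(200:1000, n(), replace = TRUE)),
                end = .data$end + sample(1000:5000, n(), replace = TRUE),
                gene_id = sprintf("gene%05d", row_number()),
                score = 0L,
                strand = sample(c("+", "-"), n(), replace = TRUE))

    list(peaks = peaks, peak_calls = peak_calls, signal = signal,
         counts = core$counts, samples = core$samples, truth = core$truth,
         states = states, genes = genes, chrom_sizes = chrom_sizes)
  })
}

#' Configuration for the survival-cohort simulator
#'
#' @param n_patients Cohort size.
#' @param baseline_hazard Event hazard per unit time in the non-risk group.
#' @param hazard_ratio_risk_group Hazard multiplier for patients who are both
#'   NOTCH-score high and CIITA low (the at-risk stratum).
#' @param censoring_rate Hazard of the independent exponential censoring
#'   process.
#' @param mutation_odds_ratio_low_ciita Odds ratio of carrying a NOTCH1
#'   mutation for CIITA-low versus CIITA-high patients.
#' @param ciita_threshold Expression level splitting CIITA low/high in the
#'   generator (the cohort's CIITA values are centred near it).
#' @param baseline_mutation_prob Mutation probability among CIITA-high
#'   patients.
#' @param seed Integer seed.
#' @return A `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_patients = 337L,
                                baseline_hazard = 0.1,
                                hazard_ratio_risk_group = 3,
                                censoring_rate = 0.05,
                                mutation_odds_ratio_low_ciita = 2,
                                ciita_threshold = 14.9,
                                baseline_mutation_prob = 0.15,
                                seed = 1L) {
  check_scalar_number(n_patients, "n_patients", lower = 4, integerish = TRUE)
  for (nm in c("baseline_hazard", "hazard_ratio_risk_group", "censoring_rate",
               "mutation_odds_ratio_low_ciita")) {
    check_scalar_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_scalar_number(baseline_mutation_prob, "baseline_mutation_prob",
                      lower = 0, upper = 1)
  check_scalar_number(seed, "seed", integerish = TRUE)
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard,
                 hazard_ratio_risk_group = hazard_ratio_risk_group,
                 censoring_rate = censoring_rate,
                 mutation_odds_ratio_low_ciita = mutation_odds_ratio_low_ciita,
                 ciita_threshold = ciita_threshold,
                 baseline_mutation_prob = baseline_mutation_prob,
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate a right-censored clinical cohort with a NOTCH/CIITA risk stratum
#'
#' Each patient gets a latent NOTCH-pathway activation level driving the four
#' score genes (HES1/HES2/HEY1/HEY2, on a log2-like expression scale), a CIITA
#' expression value inversely correlated with that activation, a NOTCH1
#' mutation flag whose odds are elevated in the CIITA-low stratum, and
#' exponential event/censoring times. Patients who are simultaneously
#' NOTCH-score high (above the cohort median) and CIITA low (at or below the
#' configured threshold) have their event hazard multiplied by
#' `hazard_ratio_risk_group`; the planted stratum is recorded in `risk_group`.
#'
#' @param config A [survival_sim_config()].
#' @return A tibble with one row per patient: `patient_id`, `hes1`, `hes2`,
#'   `hey1`, `hey2`, `ciita`, `notch1_mutated`, `time`, `event`,
#'   `risk_group` (planted truth, not an observable).
#' @export
simulate_cohort <- function(config = survival_sim_config()) {
  stopifnot(inherits(config, "survival_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    activation <- rnorm(n)
    gene <- function() 10 + activation + rnorm(n, 0, 0.5)
    hes1 <- gene(); hes2 <- gene(); hey1 <- gene(); hey2 <- gene()
    ciita <- config$ciita_threshold - 0.8 * activation + rnorm(n, 0, 1.2)

    score <- (hes1 + hes2 + hey1 + hey2) / 4
    notch_high <- score > median(score)
    ciita_low <- ciita <= config$ciita_threshold
    risk <- notch_high & ciita_low

    odds_high <- config$baseline_mutation_prob / (1 - config$baseline_mutation_prob)
    odds_low <- odds_high * config$mutation_odds_ratio_low_ciita
    p_mut <- if_else(ciita_low, odds_low / (1 + odds_low),
                     odds_high / (1 + odds_high))
    mutated <- rbinom(n, 1L, p_mut)

    hazard <- config$baseline_hazard *
      if_else(risk, config$hazard_ratio_risk_group, 1)
    t_event <- rexp(n, rate = hazard)
    t_cens <- rexp(n, rate = config$censoring_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    tibble(patient_id = sprintf("pt%04d", seq_len(n)),
           hes1 = hes1, hes2 = hes2, hey1 = hey1, hey2 = hey2,
           ciita = ciita, notch1_mutated = mutated,
           time = time, event = event, risk_group = risk)
  })
}
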