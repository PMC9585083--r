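test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(n_patients = 3, n_features = 80, frac_affected = 0.1,
                    seed = 42)
  expect_identical(simulate_paired_counts(cfg), simulate_paired_counts(cfg))

  chip_cfg <- sim_config(n_patients = 3, n_features = 60,
                         patient_effect_sd = 0.5, dispersion = 50, seed = 9)
  expect_identical(simulate_peak_experiment(chip_cfg, pc_effect_frac = 0.05),
                   simulate_peak_experiment(chip_cfg, pc_effect_frac = 0.05))

  surv_cfg <- survival_sim_config(n_patients = 50, seed = 5)
  expect_identical(simulate_cohort(surv_cfg), simulate_cohort(surv_cfg))
})

test_that("simulation does not disturb the global RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_paired_counts(sim_config(n_patients = 2, n_features = 10,
                                              frac_affected = 0, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("frac_affected = 0 plants nothing and per-pair log2FC centres on 0", {
  sim <- simulate_paired_counts(sim_config(n_patients = 4, n_features = 300,
                                           frac_affected = 0,
                                           lib_size_range = c(1, 1), seed = 11))
  expect_identical(sum(sim$truth$features$affected), 0L)
  expect_true(all(sim$truth$features$true_log2fc == 0))
  fc <- pairwise_log2fc(sim$counts, sim$samples)
  expect_lt(abs(mean(as.matrix(fc[, -1]))), 0.05)
})

test_that("pairing integrity: one sample per patient per condition", {
  sim <- simulate_paired_counts(sim_config(n_patients = 7, n_features = 20,
                                           frac_affected = 0, seed = 2))
  tab <- table(sim$samples$patient_id, sim$samples$condition)
  expect_true(all(tab == 1L))
  expect_identical(nrow(sim$samples), 14L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(n_features = 0), "n_features")
  expect_error(sim_config(frac_affected = 1.2), "frac_affected")
  expect_error(sim_config(n_features = 10, frac_affected = 0.15), "whole number")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(lib_size_range = c(2, 1)), "lib_size_range")
  expect_error(survival_sim_config(baseline_hazard = 0), "baseline_hazard")
})

test_that("planted effects are recovered in the mean per-pair log2FC (Poisson-like, large counts)", {
  # law-of-large-numbers check on the generative model: with dispersion ->
  # Inf, no patient effects and large library sizes, the mean per-pair
  # log2FC over affected features converges to the planted 1.0
  means <- vapply(1:20, function(s) {
    cfg <- sim_config(n_patients = 6, n_features = 2000, frac_affected = 0.05,
                      effect_log2fc_mean = 1.0, effect_log2fc_sd = 0,
                      patient_effect_sd = 0, dispersion = Inf,
                      lib_size_range = c(8, 8), baseline_log2_range = c(8, 12),
                      seed = s)
    sim <- simulate_paired_counts(cfg)
    fc <- pairwise_log2fc(sim$counts, sim$samples, pseudocount = 1)
    aff <- sim$truth$features$affected
    mean(abs(as.matrix(fc[aff, -1])))
  }, numeric(1))
  expect_lt(abs(mean(means) - 1.0), 0.1)
})

test_that("with no condition effect, the leading components are patient-specific", {
  # Under the patient-dominant null the condition indicator still decomposes
  # exactly onto the PC basis (its squared correlations over all components
  # sum to 1), so *some* late, noise-scale component always carries condition
  # share by chance. The meaningful null property is that the leading,
  # patient-scale components do not separate conditions.
  crit_r <- function(n) {
    tcrit <- qt(0.975, df = n - 2)
    tcrit / sqrt(n - 2 + tcrit^2)
  }
  n_pat <- 4L
  ok <- vapply(1:50, function(s) {
    cfg <- sim_config(n_patients = n_pat, n_features = 250, frac_affected = 0,
                      patient_effect_sd = 0.6, dispersion = 50, seed = s)
    chip <- simulate_peak_experiment(cfg, pc_effect_frac = 0)
    pca <- pca_over_samples(vst_transform(chip$counts))
    scan <- condition_component(pca, chip$samples)
    leading <- seq_len(n_pat - 1L)   # the patient-contrast components
    all(abs(scan$cor_condition[leading]) < crit_r(2L * n_pat))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("peak simulation emits coherent artefacts", {
  chip <- simulate_peak_experiment(
    sim_config(n_patients = 3, n_features = 100, patient_effect_sd = 0.5,
               dispersion = 50, seed = 4), pc_effect_frac = 0.1)
  # planted peaks shift with the same sign in every pair
  fc <- pairwise_log2fc(chip$counts, chip$samples)
  aff <- chip$truth$features |> dplyr::filter(affected)
  expect_identical(nrow(aff), 10L)
  fcm <- as.matrix(fc[match(aff$feature_id, fc$feature_id), -1])
  agree <- rowMeans(sign(fcm) == sign(aff$true_log2fc))
  expect_gt(mean(agree), 0.9)
  # most peaks are called in at least 2 samples
  pres <- chip$peak_calls |> dplyr::count(chrom, start, end)
  expect_gt(mean(pres$n >= 2), 0.8)
  # signal tracks match counts: value * width = count
  one <- chip$signal[chip$signal$sample_id == chip$samples$sample_id[1], ]
  ids <- sprintf("%s:%d-%d", one$chrom, one$start, one$end)
  cnt <- chip$counts[[chip$samples$sample_id[1]]][match(ids, chip$counts$feature_id)]
  expect_equal(unname(one$value * (one$end - one$start)), cnt)
})

test_that("cohort simulator reproduces its design parameters", {
  # exponential mean with negligible censoring
  coh <- simulate_cohort(survival_sim_config(
    n_patients = 4000, baseline_hazard = 1, hazard_ratio_risk_group = 1,
    censoring_rate = 1e-9, seed = 3))
  expect_true(all(coh$time > 0))
  expect_lt(abs(mean(coh$time[!coh$risk_group]) - 1), 0.06)
  expect_gt(mean(coh$event), 0.999)

  # planted hazard ratio shortens the risk group's KM median
  worse <- vapply(1:100, function(s) {
    coh <- simulate_cohort(survival_sim_config(
      n_patients = 400, baseline_hazard = 0.1, hazard_ratio_risk_group = 3,
      censoring_rate = 0.05, seed = s))
    km <- kaplan_meier(coh |> dplyr::mutate(grp = ifelse(risk_group, "risk", "rest")),
                       group = "grp")
    med <- glance(km)
    med$median_survival[med$group == "risk"] <
      med$median_survival[med$group == "rest"]
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("mutation odds ratio between CIITA strata matches the config", {
  coh <- simulate_cohort(survival_sim_config(
    n_patients = 20000, mutation_odds_ratio_low_ciita = 2, seed = 8))
  low <- coh$ciita <= 14.9
  odds <- function(p) p / (1 - p)
  or_hat <- odds(mean(coh$notch1_mutated[low])) /
    odds(mean(coh$notch1_mutated[!low]))
  expect_lt(abs(or_hat - 2), 0.3)
})
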