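# notchsig

Analysis toolkit for **paired isogenic perturbation experiments in primary
tumor B cells** — the design in which each patient's cells are split into an
empty-vector control and a counterpart transduced with a stabilized NOTCH
intracellular domain (a PEST-truncated construct mimicking the recurrent
*NOTCH1* exon 34 mutations of CLL), and every readout is analyzed
*within-pair* so that the overwhelming patient-to-patient variability of
primary material cancels out.

The package is aimed at computational biologists analyzing such paired
designs across three readouts (RNA-seq counts, H3K27ac ChIP-seq peaks,
TMT proteomics) plus clinical cohort data, and implements:

* **Per-pair fold-change consistency calling.** For features × patient
  pairs, log2FC = log2((treated + c)/(control + c)) per pair after quantile
  normalization and trimmed-mean (TMM) scaling. A feature is *up* under the
  standard rule when log2FC > 0.5 in at least half of the pairs
  (⌈n/2⌉ of n); the stringent rule additionally demands the same sign in
  every pair; the proteomics rule demands mean log2FC > 0.5 with all pairs
  sign-consistent. Down-calls are symmetric. These are threshold rules, not
  tests — no p-values are attached, by design.
* **An H3K27ac signature cascade.** Consensus peaks by base-pair union of
  per-sample calls → keep peaks present in ≥ 2 samples → variance
  stabilization (median-of-ratios size factors, log2(x/s + 1)) → PCA over
  samples → for a chosen component *k*, keep peaks whose cross-sample
  values correlate with the component's sample scores at p < 0.05
  (two-sided, t = r·√((n−2)/(1−r²))) → drop peaks in inactive chromatin
  states → keep peaks overlapping genes extended 1.5 kb upstream of their
  5′ end. In paired primary cohorts the leading components are
  patient-specific; a small later component separates control from
  construct — the cascade isolates the peaks that form it.
* **Paired subtracted signal tracks**: per base pair, the mean over pairs
  of (treated − control) signal, emitted as bedGraph.
* **Genotype-effect comparison** (e.g. trisomy-12 vs del(13q) backgrounds):
  mean per-pair log2FCs of each group's called genes, Pearson correlation
  over the union, per-set least-squares slopes with 95% bands.
* **Survival stratification.** NOTCH-activation score = mean expression of
  HES1/HES2/HEY1/HEY2; dichotomized at the median (strict >), crossed with
  high/low CIITA (master regulator of HLA class II; default threshold
  14.9), and compared by Kaplan–Meier / log-rank — both implemented from
  first principles — plus Fisher's exact test (full hypergeometric
  enumeration) for mutation enrichment between strata.
* **A synthetic-data generator** with planted ground truth (log2-additive
  patient offsets + condition effects → negative-binomial counts;
  exponential survival with a hazard-modulated NOTCH-high/CIITA-low
  stratum) so every stage is exercisable and calibratable without
  controlled-access patient data.

## Worked example

```r
library(notchsig)
library(dplyr)

# paired RNA experiment: 6 patients, 2000 genes, 5% carrying a log2FC of 1
sim <- simulate_paired_counts(sim_config(n_patients = 6, n_features = 2000,
                                         frac_affected = 0.05, dispersion = 20,
                                         seed = 7))
fc <- sim$counts |> normalize_counts() |> pairwise_log2fc(sim$samples)
calls <- call_consistency(fc, de_criterion("standard"))
count(calls, direction)
#>   direction      n
#> 1 up           130
#> 2 down         148
#> 3 not_called  1722

# chromatin signature: which component carries the condition?
chip <- simulate_peak_experiment(sim_config(n_patients = 5, n_features = 2000,
    effect_log2fc_mean = 1.5, patient_effect_sd = 0.5, dispersion = 50,
    seed = 7), pc_effect_frac = 0.02)
v   <- vst_transform(chip$counts)
pca <- pca_over_samples(v)
arrange(condition_component(pca, chip$samples), desc(abs(cor_condition)))
#>   component cor_condition explained_fraction
#> 1         5       -1.000            6.41e- 2
#> ...
sig <- select_pc_correlated_peaks(v, pca, component = 5) |>
  filter_by_chromatin_state(chip$states) |>
  annotate_to_genes(chip$genes)
nrow(sig)   # 28 signature peaks (of 40 planted)

# survival: four NOTCH-score x CIITA groups
coh   <- simulate_cohort(survival_sim_config(n_patients = 337, seed = 7))
strat <- stratify_four_groups(coh)
glance(logrank_test(strat, group = "four_group"))
#>   statistic    df  p_value
#> 1      53.9     3 1.17e-11
autoplot(kaplan_meier(strat, group = "four_group"))
```

The component table reads exactly like the diagnostic made on real paired
H3K27ac cohorts: the first components are patient-specific, while a small
mid-spectrum component (here PC5, 6.4% of variance) separates controls
from construct-transduced samples; its correlated peaks are the chromatin
signature. The log-rank test rejects because the generator plants a 3-fold
hazard on the NOTCH-high/CIITA-low stratum.

A full configurable run (`simulate → de_call → chip_signature → stratify`)
is available as `run_pipeline("inst/extdata/demo_config.yaml")`; it returns
a manifest with per-stage record counts and writes all outputs plus
`manifest.json` when given an output directory.

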