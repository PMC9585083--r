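# Pinned demonstration run: simulate -> de_call -> chip_signature -> stratify
# on synthetic data. The manifest counts of this exact configuration are
# frozen in demo_manifest_counts.tsv; reruns must reproduce them.
seed: 101
stages: [simulate, de_call, chip_signature, stratify]
simulate:
  rnaseq:
    n_patients: 6
    n_features: 2000
    frac_affected: 0.05
    effect_log2fc_mean: 1.0
    effect_log2fc_sd: 0.0
    patient_effect_sd: 0.5
    dispersion: 10
  chip:
    n_patients: 5
    n_features: 1200
    pc_effect_frac: 0.02
    effect_log2fc_mean: 1.5
    patient_effect_sd: 0.5
    dispersion: 50
  cohort:
    n_patients: 300
    hazard_ratio_risk_group: 3.0
de_call:
  criterion: standard
  fc_threshold: 0.5
  pseudocount: 1.0
  normalization: quantile+tmm
chip_signature:
  component: auto
  alpha: 0.05
  min_support: 2
  promoter_extension: 1500
stratify:
  notch_threshold: median
  ciita_threshold: median
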