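name	value
rnaseq_genes	2000
rnaseq_samples	12
chip_peaks_simulated	1200
chip_samples	10
cohort_patients	300
cohort_events	221
de_pairs	6
de_called	604
de_up	298
de_down	306
de_conflicts	10
chip_consensus_peaks	1179
chip_supported_peaks	1109
chip_component	5
chip_pc_correlated	22
chip_state_filtered	14
chip_gene_annotated	14
chip_subtracted_runs	1200
strata_sizes.notch_low.ciita_high	102
strata_sizes.notch_low.ciita_low	48
strata_sizes.notch_high.ciita_high	48
strata_sizes.notch_high.ciita_low	102
logrank_df	3
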