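# Full experimental-design configuration: 250 founders, 18 chromosomes with
# 5400 segregating sites each, an 18 000-SNP panel (1000/chromosome), 56 QTL,
# 10 random-mating burn-in generations and 40 selection cycles at the
# baseline of 400 crosses. Trait architecture (mean_dd, h2_trait) is varied
# per scenario: (0, 0.6), (0.5, 0.3), (1, 0.3), (2, 0.3), (4, 0.1).
# Running both arms at this scale refits the genomic model every cycle and
# takes on the order of hours on one CPU; see scripts/long_run.R.
n_founders: 250
n_chromosomes: 18
sites_per_chr: 5400
markers_per_chr: 1000
n_qtl: 56
mean_dd: 2
var_dd: 0.2
h2_trait: 0.3
burn_in_cycles: 10
n_cycles: 40
n_crosses: 400
progeny_per_cross: 1
stage_h2: [0.15, 0.25, 0.45, 0.65]
stage_reps: [1, 2, 3, 3]
stage_advance: [0.90, 0.80, 0.70, 0.60]
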