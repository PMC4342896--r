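# Default end-to-end pipeline configuration.
# Groups default to the full packaged cohort (null = all nine groups).
seed: 20150218
control_label: CTR
value_floor: 0
log2_floor: 0.01
groups: null
layout:
  replicates_per_sample: 4
  standard_concentrations: [0.0, 0.2, 0.4, 0.6, 0.8, 1.0]
  n_blank_spots: 4
  technical_cv_percent: 8.6
stats:
  method: dunnett
  mc_draws: 20000
clustering_tasks:
  - name: metabolic_myopathies
    groups: [CTR, ComplexI, GlycV]
    markers: [NADHs9, PYGM, bf1_over_gapdh]
    k: 3
  - name: muscular_dystrophies
    groups: [CTR, DMD, BMD, Xp21, LGMD2C]
    markers: [LDHA, bec_index, PYGM]
    k: 2
  - name: ncl
    groups: [CTR, NCL]
    markers: [PYGM, GPD1, bf1_over_ldha]
    k: 2
classifier_targets: [DMD, BMD, NCL, LGMD2C]
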