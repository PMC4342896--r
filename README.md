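# bioensig

Energy metabolism leaves a quantifiable fingerprint in diseased muscle.
Reverse-phase protein microarrays (RPMA) print nanolitre spots of biopsy
lysate and probe them one antibody per array, yielding fluorescence
intensities for a panel of nineteen enzymes and structural proteins spanning
glycogenolysis, glycolysis, fatty-acid oxidation, the Krebs cycle, the
respiratory chain and oxidative phosphorylation.  `bioensig` implements the
complete analysis of such arrays for rare neuromuscular diseases (Duchenne
and Becker dystrophies, Xp21 carriers, LGMD2C, McArdle disease / glycogenosis
type V, isolated Complex I deficiency, NCL, ICU myopathy), for researchers
who want to evaluate metabolic biomarker panels without wet-lab data — every
stage is backed by a calibrated simulator.

The pipeline:

1. **Quantification** — per marker: background from BSA blank spots, an OLS
   standard curve `I = a·c + b` through a 0–1 µg/µl dilution series,
   aggregation of quadruplicate sample spots (replicate CV
   `SCV = σ·100/|x̄|`), and inversion `amount = (x̄ − b)/a`.
2. **Normalization & signatures** — fold of control (control mean ≡ 1),
   log2-relative expression `log2(x / x̄_ctrl)` with floor 0.01, and the
   bioenergetic ratios `BEC = (βF1/Hsp60)/GAPDH`, `βF1/GAPDH`, `βF1/LDH-A`.
3. **Inference** — pooled-variance Student's t, one-way ANOVA, and a
   Monte-Carlo Dunnett many-to-one test valid for unbalanced cohorts.
4. **Clustering** — from-scratch WPGMA (weighted pair-group average,
   `d(a∪b, c) = (d(a,c)+d(b,c))/2`) on Euclidean distances of log2-relative
   profiles, tree cutting, majority cluster-to-class mapping, and
   sensitivity/specificity scoring.
5. **Interval classification** — disease calls from closed intervals on
   `βF1/LDH-A` plus one extra marker, scored with the panel's published
   convention `Sensitivity = TP/(TP+FP)`.

Published per-group parameters (mean fold ± SEM for 22 marker/ratio rows in
9 groups, n = 4…20) and the four diagnostic interval rules ship as plain-text
data and drive the cohort simulator.

## Worked example

```r
library(bioensig)

## simulate a three-group cohort (20 controls, 12 Complex I, 7 McArdle),
## print it to a noisy array, and quantify it back
spec  <- cohort_spec(reference_groups(c("CTR", "ComplexI", "GlycV")), seed = 1)
expr  <- simulate_cohort(spec)
spots <- simulate_spot_table(expr, array_layout(seed = 2))
q     <- quantify_table(spots)
q$array_scv_percent
#> [1] 8.00        # mean replicate CV, close to the configured 8.6%

foc <- fold_of_control(add_signatures(as_expression_matrix(q)), "CTR")
round(colMeans(foc[foc$class_label == "GlycV",
                   c("PYGM", "NADHs9", "GAPDH", "bf1_over_ldha")]), 2)
#>          PYGM        NADHs9         GAPDH bf1_over_ldha
#>          0.00          1.31          0.54          2.04
```

Myophosphorylase (PYGM) is absent in the McArdle group — the defining lesion
of glycogenosis type V — while the βF1/LDH-A bioenergetic ratio roughly
doubles.  Dunnett comparisons against the controls pick these up:

```r
st <- test_markers(foc[, c("sample_id", "class_label", "PYGM", "NADHs9")],
                   "CTR", mc_draws = 50000, seed = 3)
st[, c("marker", "comparison", "t_statistic", "p_adjusted", "significance_tier")]
#>   marker          comparison t_statistic p_adjusted significance_tier
#> 1   PYGM ComplexI vs control       0.915   5.87e-01                ns
#> 2   PYGM    GlycV vs control      -3.963   6.80e-04           p<0.001
#> 3 NADHs9 ComplexI vs control       5.821   1.21e-06           p<0.001
#> 4 NADHs9    GlycV vs control       1.820   1.40e-01                ns
```

Clustering the log2-relative profiles of a diagnostic three-marker panel:

```r
lr <- log2_relative(expr[, c("sample_id", "class_label",
                             "NADHs9", "PYGM", "bf1_over_gapdh")], "CTR")
lk <- wpgma_linkage(euclidean_distances(lr))
cluster_performance(cut_tree(lk, 3), expr$class_label, "CTR")
#>      class  n sensitivity_percent tp_fp_percent
#> 1 ComplexI 12                   0            NA
#> 2      CTR 20                 100          62.5
#> 3    GlycV  7                 100         100.0
#> control specificity: 100.0% | pooled pathologic sensitivity: 36.8% | pooled specificity: 100.0%
```

The McArdle cluster separates perfectly (PYGM = 0 sits 6.6 log2 units from
everything), while the Complex I group — simulated as independent normal
markers with SD = SEM·√n — overlaps the controls too much for an average-type
linkage to isolate it; the methods vignette analyses why this differs from
the real biopsies.  `write_newick(lk)` exports the dendrogram.

The interval classifier:

```r
diagnostic_rules()$DMD
#> DMD: bf1_over_ldha in [2.9, 4.1] AND PYGM in [0.1, 0.3]
interval_rule_benchmark(diagnostic_rules()$DMD, reps = 200, seed = 7)$mean_sensitivity
#> [1] 100        # controls essentially never satisfy both intervals
```

A full end-to-end run (simulate → quantify → normalize → test → cluster →
classify, all intermediates as CSV/Newick/JSON):

```r
report <- run_pipeline(pipeline_config(), outdir = "rpma_out")
```

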