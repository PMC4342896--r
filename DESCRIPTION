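Package: bioensig
Title: Bioenergetic-Signature Analysis of Reverse-Phase Protein Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification and classification of energy-metabolism protein
    markers assayed on reverse-phase protein microarrays (RPMA) of muscle
    biopsies.  Simulates cohorts and raw spot-intensity tables with realistic
    replicate noise, calibrates spot fluorescence against a serial-dilution
    standard curve, normalizes expression to fold of control, computes
    bioenergetic-signature ratios (BEC index, beta-F1/GAPDH, beta-F1/LDH-A),
    tests group differences (Student's t, one-way ANOVA, Monte-Carlo Dunnett
    many-to-one comparisons), clusters expression profiles with from-scratch
    Euclidean/WPGMA linkage scored by classification sensitivity and
    specificity, and evaluates interval-rule disease classifiers for rare
    neuromuscular diseases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
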