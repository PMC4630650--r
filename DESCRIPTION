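Package: dexmet
Title: Time-Course Metabolome Analysis of Glucocorticoid Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for repeated-measures plasma
    metabolomics time courses with a mid-study treatment intervention.
    Provides pooled-reference normalization, log10 transformation and
    autoscaling; time-matched mixed-effects ANOVA per metabolite with
    Benjamini-Hochberg correction and linear-scale fold-change ratios;
    a complete STATIS multi-table ordination (per-subject cross-product
    matrices, RV-coefficient interstructure, eigenvector table weights,
    compromise eigendecomposition and projections); two-class PLS-DA with
    leave-one-subject-out cross-validated Q2; and a Kendall rank-stability
    statistic that identifies metabolites with individual-specific, time-
    stable levels (metabolic phenotypes). A synthetic-cohort generator with
    circadian trends, stable subject phenotypes and post-dose effect profiles
    supplies ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    cluster,
    jsonlite
Config/testthat/edition: 3
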