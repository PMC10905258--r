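Package: batcheval
Title: Batch-Effect Evaluation for Multi-Dataset Transcriptomics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies batch effects in merged single-cell and spatially
    resolved transcriptomics datasets. Runs a statistical test battery
    (one-way ANOVA on per-observation totals, Kruskal-Wallis H, pairwise
    Kolmogorov-Smirnov, Cramer's V contingency association), trains a
    focal-loss neural domain classifier whose held-out accuracy measures
    batch separability, computes neighborhood-mixing and
    biology-preservation metrics (k-BET, local inverse Simpson index,
    silhouette coefficients) with their F1 combiners, aggregates them into
    a composite score, benchmarks pluggable batch-correction methods, and
    renders a multi-page HTML report with a recommendation. Includes a
    seeded negative-binomial simulator of multi-batch expression data with
    controllable batch effect for testing and demonstration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    patchwork,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
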