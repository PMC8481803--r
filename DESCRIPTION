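Package: trailkit
Title: Enrichment, Network Path, and Regulator Analysis for Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for identifying deregulated biological
    processes in bulk, time-series, and single-cell gene expression data.
    Provides per-gene differential scoring (log fold change, Welch t,
    Wilcoxon rank-sum), over-representation analysis with exact
    hypergeometric tails, functional-class-scoring statistics including a
    weighted running-sum (GSEA-style) enrichment score with a permutation
    null, search for maximally deregulated simple paths in directed gene
    networks, prioritization of transcriptional regulators from
    regulator-target interactions with activator/repressor calls, a
    per-cell enrichment workflow with group activity testing and
    pseudo-bulk aggregation, time-course filtering and k-medoids
    clustering with per-cluster enrichment, and seeded synthetic-data
    generators with known ground truth for every pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    methods,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
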