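Package: pathwalker
Title: Composite Regulatory Module Discovery and Master-Regulator Search
    for Methylation-Driven Pathway Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering candidate epigenetic biomarkers by
    integrating DNA methylation and gene expression data with regulatory
    sequence analysis. Implements Match-style position weight matrix
    scanning, F-Match binding-site enrichment with per-matrix cutoff
    optimisation, composite-module models of regulatory regions whose
    score is optimised by a genetic algorithm to correlate with a
    quantitative per-sequence trait, context-weighted key-node search for
    master regulators in signalling networks with positive feedback loop
    detection, CpG-gene correlation analysis, and biomarker panel
    construction with repeated random-split classifier evaluation.
    Includes synthetic data generators so the full workflow can be
    exercised end to end without proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    e1071,
    igraph,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
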