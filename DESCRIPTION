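Package: ccreg
Title: Candidate Cis-Regulatory Element Registries and Epigenetic
    Regulatory Potential Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a registry of candidate cis-regulatory elements
    (cCREs) from replicate nuclease-accessibility peak calls and
    multi-cell-type epigenetic state maps, quantifies the regulatory
    landscape (state coverage, active-cCRE dynamics, state transitions,
    aggregated signal profiles), and fits a multivariate linear model of
    gene expression on chromatin-state proportions at promoters and
    pooled distal cCREs. The fitted coefficients define an epigenetic
    regulatory potential (eRP) score per cCRE and cell type, evaluated by
    leave-one-out cross-cell-type adjusted r-squared and exported as
    thresholded cCRE-target-gene pairs with optional TAD restriction. A
    lineage-structured synthetic-data generator with known ground truth
    supports development and validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    limma,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
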