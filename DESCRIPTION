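Package: loopdyn
Title: Promoter-Interaction Dynamics from Chromatin Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing diet- or condition-induced
    rewiring of promoter-anchored chromatin interactions. Builds, merges and
    iteratively balances binned Hi-C contact matrices; calls A/B compartments,
    insulation-based TADs and distance-stratified z-score loops with aggregate
    peak analysis; scores promoter-capture interactions against a negative
    binomial distance-decay background; tests interactions, ChIP peaks and
    genes for differential abundance with an exact negative binomial test;
    classifies dynamic loops into rewired versus preformed-activated
    categories; and links loop classes to gene expression with rank tests,
    Monte-Carlo shuffle overlap statistics and matched-control annotation
    overlap. A synthetic-data module plants compartments, TADs, loops,
    co-bound peak sets and differential expression with known truth so the
    whole pipeline is testable without external data.
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
    IRanges,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
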