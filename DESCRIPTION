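Package: dynachip
Title: Dynamic Transcription Factor Occupancy Analysis for ChIP-chip Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing dynamic transcription
    factor-DNA binding measured by two-colour ChIP-chip tiling arrays over a
    stress time course. Provides two-stage probe normalization
    (density-weighted loess within arrays, quantile across arrays),
    deconvolution-based binding-peak calling with bootstrap significance,
    peak-to-gene assignment with Fisher-combined evidence, clustering of
    dynamic occupancy profiles, binding-expression (GE-ChIP) Spearman
    correlation for activator/repressor calls, de novo discovery of a
    palindromic cis-regulatory motif by expectation-maximization, co-binding
    geometry analysis of sequence-specific and general transcription factor
    sites with a resampling null, hypergeometric functional enrichment, and
    growth-phenotype scoring. A synthetic-data generator plants known ground
    truth (peaks, dynamics, motifs, co-binding distances, growth rates) so
    every stage can be benchmarked against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    pracma,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    GenomicRanges,
    IRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
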