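Package: riddseq
Title: Ribosome-Profiling Analysis of Ire1-Dependent mRNA Decay and No-Go Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting endonucleolytic mRNA cleavage and ribosome
    stalling from ribosome-profiling data in fission yeast. Builds
    size-classified footprint 3'-end density tracks from aligned reads, calls
    UPR-induced cleavage/stall sites at single-nucleotide resolution with
    mRNA-Seq correction, classifies sites by UG/C motif and reading frame,
    computes equal-weight metagene averages, disome localization and 14/28-nt
    periodicity via the autocorrelation power spectrum, and scores
    colony-size fitness screens by standardized log-ratios. Includes a
    mechanistic synthetic-data simulator of iterative no-go-decay cleavage
    templated by stalled ribosomes, so every stage of the pipeline can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
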