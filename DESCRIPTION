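Package: paraseek
Title: Paralog Discovery from Multiplexed Nanopore Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and sequences tandem gene paralogs from demultiplexed
    long-read amplicon data. Implements primer-based in-silico amplicon
    extraction with IUPAC-degenerate matching, NanoFilt-style length and
    quality filtering, greedy identity-threshold clustering with automatic
    selection of the identity threshold, majority-vote consensus polishing
    with overclustering control, reference-guided CDS annotation with
    homopolymer frameshift repair and gene-hallmark validation, and a
    ground-truthed read simulator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
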