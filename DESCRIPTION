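Package: slclip
Title: Anchored iCLIP Analysis of Histone mRNA Stem-Loop Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, desk-scale iCLIP analysis pipeline for
    protein binding to replication-dependent histone mRNAs. Provides a
    seeded synthetic-data generator (toy genome with histone gene models,
    truncation-type iCLIP libraries with UMIs and sample barcodes,
    fluorescence-polarization titrations), read processing (quality
    filtering, demultiplexing, adapter trimming, UMI deduplication, exact
    alignment), single-nucleotide crosslink and read-termination tracks,
    a negative-binomial Wald test of IP versus control binding with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    three-anchor binned metagene profiles around the histone 3' stem-loop,
    and Hill-equation fitting of fluorescence-polarization binding curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
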