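Package: gatecall
Title: Deconvolution of Sorted Combinatorial Surface-Display Libraries from
    Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening combinatorial promoter x signal-peptide
    yeast surface-display libraries by sort-seq. Models a modular Golden
    Gate part grammar, enumerates the combinatorial design space, simulates
    FACS sorting of cells into fluorescence gates and nanopore-like long
    reads of barcoded amplicon pools, and deconvolves pooled reads natively:
    error-tolerant dual-barcode demultiplexing, full-amplicon length
    filtering, orientation by a 3' marker sequence, local-alignment
    annotation of reads against part references (with GFF3 export),
    genotype calling with truncation detection, and per-gate genotype
    abundance and enrichment reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    generics,
    rlang,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
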