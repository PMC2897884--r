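Package: rnarefine
Title: Validate and Correct Predicted Gene Models with RNA-Seq Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects per-base and per-junction disagreements between predicted
    gene models and RNA-seq read coverage, repairs them by probe-seeded
    consensus assembly of the reads (bridging internal deviations and
    extending gene termini), realigns the repaired transcript to the genome
    with a splice-aware Smith-Waterman variant using asymmetric gap penalties,
    and classifies every model as validated, corrected, or failed. Includes a
    ground-truth synthetic fixture generator (genomes, corrupted gene models,
    tiled or random fixed-length reads), a cumulative-binomial annotation
    enrichment statistic, GFF3/FASTA/FASTQ input and output, and tidy
    accessors and plots for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
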