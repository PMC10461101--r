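Package: mirwoodnet
Title: Small RNA Discovery and miRNA-TF-mRNA Network Analysis for Wood
    Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, testable reimplementation of a small-RNA-seq
    analysis pipeline for reaction wood (tension wood) studies: read
    cleaning and exact genome mapping, known and novel miRNA discovery by
    hairpin folding, reads-per-million normalization and differential
    abundance testing, plant-style miRNA target prediction with a
    position-weighted expectation score, expression anti-correlation
    validation of targets, tripartite miRNA-TF-mRNA network assembly,
    hypergeometric pathway enrichment, and 2^-ddCt qPCR quantification.
    Includes a synthetic-data generator that plants hairpin precursors,
    tissue-differential miRNA abundance, anti-correlated targets, TF
    co-expression structure and an enriched pathway, with a
    machine-readable ground-truth table for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
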