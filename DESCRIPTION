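Package: tgmap
Title: Mapping Transgene Integration Sites from Nanopore Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates and characterizes transgene integration sites from
    long-read sequencing data. Identifies marker-bearing and chimeric
    host/transgene reads, estimates tandem-array copy number from marker
    match counts and fold-coverage, calls integration boundaries and the
    host deletion they flank, detects array-internal inversions and
    co-integrated foreign (e.g. bacterial) DNA, verifies the integrity of
    genes neighboring the insertion, and quantifies copy number from qPCR
    Ct tables by relative quantification. Includes a synthetic-locus and
    noisy long-read simulator with full ground truth, a strand-aware k-mer
    seed-and-chain aligner with PAF import/export, and windowed nucleotide
    dot-plot computation with diagonal-run segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    graphics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
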