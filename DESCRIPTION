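Package: genoskim
Title: Genome-Skim Assembly of Plastomes and Ribosomal DNA with Barcode
    Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recovering high-copy genomic elements from shallow
    shotgun sequencing ("genome skims") of plants. Implements paired-end
    read quality filtering, canonical k-mer indexing, seed-and-extend
    De Bruijn graph assembly of the circular quadripartite chloroplast
    genome and of the tandem nuclear ribosomal DNA cluster, targeted
    extraction of the standard barcode markers matK, rbcL and ITS2 by
    translated and nucleotide local alignment, and the per-library
    success-rate accounting and group comparisons used in large
    herbarium and silica-dried sequencing campaigns. A paired-end read
    simulator with preservation presets generates annotated toy genomes
    so that the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
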