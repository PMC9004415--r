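Package: paleofossil
Title: Finding, Filtering and Dating Protein Fossils in Genomic DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects degraded remnants of formerly protein-coding DNA
    ("protein fossils", from transposable elements or host genes) by
    frameshift-aware local DNA-to-protein alignment with a 64x21 codon
    log-odds scoring model and Karlin-Altschul significance, applies the
    exclusion and overlap-resolution filters used in fossil annotation,
    reduces pairwise genome alignments to confident orthologous context
    (one-to-one selection, coding pruning, linked-alignment filtering),
    dates fossils by conservation across genome pairs, classifies repeats
    of unknown type, reports long-range split-fossil ("genome tectonics")
    pairs, and ships a synthetic-genome simulator with planted ground
    truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    igraph,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
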