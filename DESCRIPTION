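Package: numtsome
Title: Detection, Assembly and Evolutionary Analysis of Nuclear
    Mitochondrial Sequences (NumtS)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising the NumtSome, the collection of
    nuclear sequences of mitochondrial origin (NumtS) in a genome. Detects
    mtDNA-derived fragments with a built-in seed-and-extend aligner or from
    BLAST tabular output, purges mitochondrial contamination contigs by
    occupancy, assembles high-scoring pairs into NumtS using a genomic
    distance and repeat-bridging rule, profiles per-base coverage along the
    circular mitochondrial genome and calls insertion hotspots, quantifies
    repeat-element co-occurrence in NumtS loci and flanks, dates insertions
    by a profile-HMM log-odds score difference between mitochondrial and
    flanking-region profiles, and reconstructs NumtS phylogenies with
    Kimura two-parameter distances, neighbor joining and a strict-clock
    calibrated timetree. Ships a synthetic genome generator that plants
    age-stratified NumtS with ground truth so every stage is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
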