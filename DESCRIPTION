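Package: phasir
Title: Small RNA Profiling, miRNA Annotation and Phased siRNA (PHAS) Locus
    Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for plant small RNA sequencing analysis: collapses
    and length-filters sRNA libraries, normalizes abundances to reads per 15
    million, profiles read-size distributions, calls miRNA loci from genome
    alignments using hairpin precursor criteria (secondary-structure folding,
    miRNA:miRNA* duplex geometry, locus dominance), scores miRNA-target
    complementarity with a position-weighted penalty scheme and predicts
    cleavage sites, and detects 21-nt phased siRNA (PHAS) loci with a
    sliding-window register scan, a hypergeometric phasing P value, a phasing
    score, miRNA trigger assignment and tissue abundance matrices. Includes a
    deterministic synthetic-data generator that plants miRNA hairpins and
    phased loci in toy genomes so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
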