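Package: divflow
Title: Divergence-with-Gene-Flow Inference from Joint Site-Frequency
    Spectra and Genome Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to reconstruct the divergence history of a pair of
    sister species from whole-genome polymorphism data. Implements a
    two-deme structured-coalescent simulator with piecewise-constant
    migration epochs, rejection approximate Bayesian computation (ABC)
    model selection on the joint site-frequency spectrum across five
    divergence-with-gene-flow scenarios, hard site filters and LD pruning
    for variant tables, fourfold-degenerate site extraction from a
    reference and annotation, 30 kb windowed genome scans (nucleotide
    diversity, Tajima's D, absolute divergence D_XY, Weir-Cockerham F_ST)
    with early-diverged-window classification, per-gene McDonald-Kreitman
    selection tests, and a synthetic-data generator that produces
    standards-compliant fixtures with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
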