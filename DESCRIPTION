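Package: minicoi
Title: Degenerate-Primer Design and COI Mini-Barcode Metabarcoding Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and evaluating degenerate PCR primers within
    the 658 bp COI barcoding region and for processing the resulting
    mini-barcode amplicon reads. Covers IUPAC/degenerate-oligo arithmetic,
    Shannon-entropy profiling of barcode alignments with conserved-window
    discovery and degenerate-consensus generation, predator-specific blocking
    primer design, IUPAC-aware in-silico PCR with mismatch-distribution
    reports, a reading-frame-aware read-QC pipeline (hierarchical
    demultiplexing, primer and length filters, stop-codon/frameshift/indel
    classification with single-frameshift repair, a two-parent chimera
    screen), greedy centroid OTU clustering with identity-threshold taxonomic
    assignment, diet summary tables and rarefaction. Includes seeded
    generators for codon-structured synthetic data so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
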