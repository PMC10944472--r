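Package: surs
Title: Design and SORT-Seq Characterization of Synthetic Upstream Regulatory Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing motif-based synthetic upstream regulatory
    sequence (sURS) oligo libraries and characterizing them by sort-and-sequence
    (SORT-seq) massively parallel reporter assays. The package converts position
    weight matrices to degenerate mixed-base (K/M) motifs, designs a binding-site
    free "desert" chassis, enumerates 0-3 motif arrangements with constrained
    barcodes, demultiplexes FACS-bin reads, computes bin-weighted mean
    fluorescent expression, identifies boosting and attenuating motifs by exact
    minimum-hypergeometric (mHG) enrichment, and predicts regulatory output with
    a mechanistic motif-additive model and a small convolutional sequence model.
    A seeded SORT-seq simulator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
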