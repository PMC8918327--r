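Package: sydescan
Title: Short Linear Motif Scanning and Interactor Prediction for the SYDE
    C2-RhoGAP Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an in-silico pipeline for predicting short linear
    motif (SLiM) mediated interactors of the SYDE1/SYDE2 RhoGAP proteins:
    a curated motif catalog with background-probability scoring, a
    fold-index disorder surrogate with an import path for external
    predictor output, ortholog conservation mapping through multiple
    alignments, Needleman-Wunsch percent identity for domain homology,
    a distance-based neighbor-joining phylogeny with column-bootstrap
    supports, and assembly of a tiered protein interaction network.
    Ships a synthetic ortholog-family generator with ground truth so the
    full pipeline is testable end to end without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
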