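Package: clonetrace
Title: Clonal Barcode Analysis for Single-Cell Lineage Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell lineage tracing (scLT) experiments from
    raw barcode-cell assignments to clone-level statistics. Resolves
    multi-barcode cells into unique clones, filters high-confidence clones,
    computes clone sizes and barcode detection metrics, normalizes clone
    fate outcomes, calls clone fate bias with one-sided Fisher's exact
    tests under Benjamini-Hochberg FDR control, infers lineage
    relationships between cell types from Spearman correlation of barcode
    signatures, performs fate-bias-conditioned differential expression
    (negative binomial) and accessibility (Wilcoxon) testing, and scans
    differentially accessible regions for transcription-factor motifs at an
    exact score p-value cutoff. A synthetic-experiment generator with a
    planted ground-truth ledger makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    ape,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
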