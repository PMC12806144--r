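Package: crefdual
Title: Dual Eigen-Analysis of Promoter Cis-Regulatory Element Frequency Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genes-by-motifs cis-regulatory element frequency (CREF)
    matrices from promoter scans with position weight matrices, decomposes
    them robustly into a low-rank part plus sparse outliers (inexact
    augmented Lagrange multipliers), extracts polarized dual eigen-modules
    by singular value decomposition, quantifies module stability through
    spectral gaps and first-order eigenvector perturbation theory, compares
    motif-eigenvectors across species (Pearson correlation, Deming
    regression, rotation angles), performs rank-based Wilcoxon gene-set
    enrichment along gene-eigenvectors, and analyses transposable-element
    motif content (motifs present on repeat consensus sequences). A
    synthetic-data generator with planted low-rank structure, sparse
    corruption, count noise, planted motif occurrences and planted
    enrichment makes the whole pipeline testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
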