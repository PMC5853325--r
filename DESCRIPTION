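Package: c4gradient
Title: Comparative Transcriptomics of C3 and C4 Leaf Maturation Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of leaf developmental-gradient
    transcriptomes across congeneric C3 and C4 species. Provides a synthetic
    multi-species expression-matrix generator with planted ground truth,
    readers and writers for expression, annotation-map, gene-category and
    candidate-list tables, TPM and Z-score normalization, base/mid/tip
    transcript-behaviour classification, pathway-consistent differential
    expression under a two-by-two species design, principal components and
    sample-correlation analysis, hypergeometric category over-representation
    with Benjamini-Hochberg control, and intersection of external C4-candidate
    gene lists with the cross-species detection universe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
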