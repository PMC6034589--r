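Package: epiself
Title: Human-Likeness and Tolerance-Oriented Analysis of HLA Class II Epitope Presentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline contrasting peptide presentation by HLA-DQ and
    HLA-DR molecules. Provides k-tuple-distance redundancy filtering of epitope
    sets, 5-mer proteome-similarity profiles with a label-permutation
    significance test, paired DQ/DR assay contingency analysis with Fisher's
    exact test, allele-by-species recognition matrices with Ward clustering and
    position-specific scoring-matrix confirmation, and regression/rank-based
    analysis of the relationship between auto-epitope binding and autoimmune
    disease risk. A seeded synthetic-data module emulates the epitope, proteome,
    allele-catalog, association-table and binding-predictor inputs with
    plantable effect sizes so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    lmtest,
    stats,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
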