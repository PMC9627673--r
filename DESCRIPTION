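Package: metabotyper
Title: Metabolic Typing of Cell Line Panels from Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for large multi-batch untargeted metabolomics
    screens of cell line panels: total-ion-current quality filtering,
    benchmarking of sample-variance, signal-drift and batch-effect
    normalization methods against five replicate-based reproducibility
    criteria, principal-component pathway activity scoring on curated
    pathway definitions, unsupervised metabolic typing by Ward clustering
    with a dendrogram-branch multi-omics association scan under global
    Storey-Tibshirani false discovery control, 13C isotopologue analysis
    (natural-abundance correction, fractional contributions, type-wise
    fractional differences), lipid class summaries, and enrichment of
    pathway or gene sets in ranked lists including pre-ranked gene set
    enrichment analysis. Ships a synthetic-data generator that emulates
    the statistical structure of such screens so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    pracma,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
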