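Package: ProteoVasc
Title: Co-Expression Network Analysis of Multiplexed Cerebrovascular Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage inference pipeline for tandem-mass-tag (TMT)
    proteomic abundance matrices from cerebrovascular-enriched brain tissue:
    sum-scaling and missingness handling, batch correction by iterative
    two-way median polish of sample/pooled-standard ratios (TAMPOR),
    nonparametric bootstrap covariate regression, signed weighted
    co-expression network construction with biweight midcorrelation and
    topological overlap, eigenprotein-based module refinement, module- and
    protein-level trait association scans (linear, logistic, proportional
    odds) with multiplicity control, permutation-null module enrichment, and
    cross-network module preservation (Zsummary). Includes a seeded
    synthetic-data generator planting module, batch, covariate, and trait
    structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    withr,
    jsonlite,
    yaml,
    fgsea,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
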