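Package: qphar
Title: Quantitative Pharmacophore Activity Relationship Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative (regression) pharmacophore models from small
    sets of 3D molecules or pharmacophores with activity annotations. A
    consensus (merged) pharmacophore is constructed by rigid alignment of all
    training samples to a template, per-type single-linkage clustering of the
    pooled features, representative-feature selection and removal of
    ambiguous features; aligned samples are then featurized against the
    representatives by inverse feature distances and regressed against
    log-scale activities with deliberately restricted learners. Includes
    rule-based pharmacophore perception from SDF conformers, dataset-curation
    filters (activity-range and heterogeneity gates), stratified splits and
    cross-validation for regression endpoints, feature-count and
    physico-chemical baseline models with min/max applicability domains, a
    seeded synthetic SAR-series generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    ChemmineR,
    ChemmineOB,
    mixOmics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
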