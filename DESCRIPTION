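Package: nichecast
Title: Maximum-Entropy Ecological Niche Modelling and Climate-Scenario
    Projection for Presence-Only Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background ecological niche modelling built around a
    from-scratch L1-regularized maximum-entropy engine with linear, quadratic,
    product, threshold and hinge feature classes. Provides gridded
    environmental data containers with ESRI ASCII grid input/output,
    occurrence cleaning and one-record-per-cell spatial thinning, kernel
    density sampling-bias surfaces, Pearson-correlation plus
    percent-contribution variable selection, k-fold cross-validated AUC,
    jackknife variable importance, marginal response curves, maximum
    sensitivity-plus-specificity thresholding with four-class suitability
    maps, projection onto perturbed-climate raster stacks, and a seeded
    synthetic-world generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'ascii-grid.R'
    'occurrences-io.R'
    'synthetic-world.R'
    'fixtures.R'
    'occurrence-prep.R'
    'maxent-features.R'
    'maxent-fit.R'
    'maxent-predict.R'
    'variable-selection.R'
    'evaluation.R'
    'suitability.R'
    'pipeline.R'
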