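Package: bagexpr
Title: Gene Expression Prediction from Bags of Whole-Slide Image Tile Features
Version: 0.1.0
Authors@R:
    person("bagexpr", "developers", email = "bagexpr@example.org", role = c("aut", "cre"))
Description: Weakly supervised, multi-task regression of bulk gene expression
    from bags of whole-slide-image tile features. A per-tile multilayer
    perceptron shared across tiles is trained with stochastic top-k
    aggregation and evaluated with a deterministic multi-k average, so that
    per-tile scores double as virtual spatialization maps. Includes supertile
    preprocessing (spatial k-means with feature averaging), gene filtering and
    log normalization, patient-grouped stratified cross-validation, an
    empirical null from untrained models with Holm-Sidak and
    Benjamini-Hochberg corrections, a pathway-versus-random-lists resampling
    test, and a two-hospital transfer harness that reuses the model's latent
    transcriptomic representation for small-cohort binary classification.
    Ships a synthetic cohort generator so the full pipeline runs at desk
    scale with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
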