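Package: treerange
Title: Ensemble Species Distribution Modelling and Dispersal Simulation for Tree Range Forecasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for forecasting tree species
    range shifts under climate change: occurrence cleaning and spatial thinning,
    bioclimatic predictor derivation with collinearity screening, change-factor
    climate downscaling over a regional-climate-model ensemble, an ensemble
    species distribution model (six families, surface-range-envelope
    pseudo-absences, prevalence weighting, TSS-based binarization, block
    cross-validation, permutation importance, MESS extrapolation masks), a
    stochastic cellular-automaton seed-dispersal simulation with trait-derived
    kernels, and land-use masking. A synthetic-world generator with known
    ground truth (Gaussian niches, biased sampling, pseudo-RCM anomaly
    ensembles, fractional forest cover) makes every stage verifiable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    xgboost,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
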