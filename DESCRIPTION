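Package: chlamyRSM
Title: Two-Round Response-Surface Regression of Microalgal Bioenergetic
    Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design-of-experiments and response-surface multiple regression
    pipeline for screening environmental drivers of photosynthesis and
    respiration in Chlamydomonas reinhardtii. Builds near-orthogonal
    two-level fractional-factorial designs with replicated center points,
    encodes linear, quadratic and interaction effects (including a
    two-level ordinal CO2 factor), fits standard least squares with the
    full ANOVA toolbox (whole-model, per-effect and lack-of-fit tests,
    beta-weights, AICc, R2/RMSE diagnostics), runs a two-round model
    selection (AICc forward stepwise with effect heredity, then p-ordered
    backward pruning under a lack-of-fit / R2 stopping rule), simulates
    response profiles and quadratic optima from the fitted or published
    models, and validates by k-fold cross-validation and against new
    measured factor combinations. A synthetic-data generator emulating the
    original 42-run study supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
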