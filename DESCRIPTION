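Package: paindex
Title: Personalized Advantage Index Pipelines for Treatment Selection
    in Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates personalized advantage index (PAI) models
    for two-group treatment comparisons from repeatedly measured outcomes:
    mixed-model calculated change scores, all-relevant predictor screening
    with shadow features and random forests, bootstrap-stabilized stepwise
    AIC refinement, leave-one-out counterfactual outcome prediction, and
    optimal-versus-suboptimal randomization contrasts. Ships a synthetic
    randomized-trial generator with configurable treatment-by-predictor
    interactions so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
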