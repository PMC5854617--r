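Package: cascadeSDM
Title: Cascaded Neural Network Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Presence/absence species distribution modelling with cascaded
    feed-forward neural networks. Biotic co-predictor species are screened by
    tetrachoric correlation and a kappa-improvement criterion against the
    confidence interval of an environment-only baseline; environment-only
    sub-models are then trained for the selected co-predictors and their
    predicted occurrence probabilities are wired into the target-species
    network, so the assembled cascade predicts from environmental inputs
    alone. Includes ROC-based cutoff optimisation, Cohen's kappa with
    confidence intervals, stratified k-fold cross-validation, three variable
    importance methods (Lek profiles, input perturbation, connection
    weights), and a seeded virtual-community simulator for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr,
    yaml
Config/testthat/edition: 3
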