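Package: prforest
Title: Probabilistic Random Forests for Data with Uncertain Class Labels
Version: 0.1.0
Authors@R: person("prforest", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains probabilistic random forest (PRF) classifiers in which
    class labels (and optionally input features) are probability functions
    rather than deterministic values. Samples propagate to both children of
    a split with Gaussian crossing probabilities and splits are scored with
    a modified Gini impurity over probability-weighted class fractions.
    Includes the three standard policies for handling uncertain labels
    (exclusion, naive acceptance, probabilistic assignment), nested
    stratified k-fold cross-validation with inner-loop hyperparameter
    selection and confirmed-label-only metrics, and a seeded generator of
    synthetic clinical cohorts with a confirmed/post-hoc label mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
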