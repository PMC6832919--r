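Package: alsord
Title: Ordinal Disease-State Modelling of ALS Functional Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling amyotrophic lateral sclerosis (ALS) disease
    state from clinical-trial visit tables shaped like the PRO-ACT database.
    Provides a synthetic cohort generator with known ground truth, first/last
    visit data preparation under three semi-temporal settings, J3
    scatter-criterion feature selection, ordinal classifiers (cumulative link
    models, ordinal decision trees with absolute-error impurity, cumulative
    probability trees) evaluated against multi-class and random-forest
    baselines by ten-fold cross-validated mean absolute error, variance-based
    predictor importance, hierarchical grouping of the ten ALSFRS items,
    MDL-discretized Bayesian-network structure learning by cross-validated
    risk with Markov-blanket extraction, and severe-versus-mild value
    combination analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    MASS,
    nnet,
    randomForest,
    jsonlite,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
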