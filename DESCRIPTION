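Package: pnvalence
Title: Olfactory Projection-Neuron Ensemble Coding of Appetitive Valence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking odor-evoked projection-neuron (PN) ensemble
    activity in the insect antennal lobe to innate and learned appetitive
    behavior (the palp-opening response, POR). Provides a synthetic-data
    generator for valence-structured Poisson spiking populations and POR
    behavior, preference-index and binomial valence-class statistics,
    threshold-based PN response classification, PCA state-space trajectories,
    correlation-distance clustering and cosine-angle similarity of ensemble
    codes, a sigmoid-squashed linear regressor from ensemble activity to POR
    probability with leave-one-out cross-validation and shuffled controls, an
    L1-regularized mapping from time-varying ensemble activity to POR
    dynamics, and a Hebbian neuron/anti-neuron conditioning model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
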