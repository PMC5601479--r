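Package: DeepCox
Title: Deep Survival Networks Trained by Cox Partial-Likelihood Backpropagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feed-forward neural networks with a Cox proportional-hazards
    output layer, trained by backpropagating the negative log partial
    likelihood with full-batch line-search gradient descent and dropout
    regularization. Includes Gaussian-process Bayesian optimization of the
    network design (depth, width, dropout, activation), Harrell's
    concordance index and a randomized-holdout evaluation protocol, risk
    backpropagation for per-patient feature attribution with preranked
    gene-set export, dataset preprocessing and multi-cohort merging for
    transfer learning, and a calibrated right-censored survival simulator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    lhs,
    optparse,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
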