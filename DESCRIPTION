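Package: stlearn
Title: State-Transition Learning Models for Sequential Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators, decision models and fitting machinery for studying
    how people learn probabilistic action-to-state transitions. Implements a
    one-step revaluation task, the two-step task and a multi-goal pursuit
    task with drifting transitions; an incremental state-transition learner
    (ISTL) and a counting ("Typical") transition model embedded in a hybrid
    model-based/model-free chooser; a four-strategy integrated model for
    multi-goal pursuit; hierarchical model fitting by iterative importance
    sampling with model comparison and parameter/model recovery studies;
    model-agnostic model-basedness metrics, trait regressions and mediation;
    hierarchical Bayesian logistic regression with ROPE/HDI decisions;
    exploratory factor analysis utilities with parallel analysis; and a
    synthetic-cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    rjags,
    coda,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
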