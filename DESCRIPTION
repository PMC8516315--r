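Package: vitrace
Title: Variable-Interval Foraging Simulation and Choice-History Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the discrete variable-interval (VI, "baiting") reward
    schedule used in two-alternative foraging experiments and provides the
    full set of decision agents studied on it: an omniscient Oracle, a
    Bayesian particle-filter inference agent, an optimal recursive
    reinforcement-learning (LK) model, the double-trace (DT) model with fast
    and slow choice traces, and a family of comparison Q-learning variants.
    Includes lagged elastic-net logistic regression of reward and choice
    history effects, teacher-forced likelihood evaluation with an
    annealing-style parameter search and cross-validated model comparison
    (negative log-likelihood, AUC), regret-based harvesting-efficiency
    analysis and in-environment parameter optimisation, and synthetic-data
    generators for parameter-recovery studies. All user-facing functions take
    and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
LinkingTo:
    Rcpp
Config/testthat/edition: 3
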