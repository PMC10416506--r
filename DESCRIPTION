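Package: symptomnet
Title: Ising Network Analysis of Binary Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates symptom networks from binary (present/absent) item
    data using the eLasso approach: each item is regressed on all others
    with an L1-penalized logistic regression, the penalty is selected by
    the Extended Bayesian Information Criterion, and the two directed
    coefficients per pair are combined under an OR- or AND-rule into a
    weighted Ising network. Includes strength and expected-influence
    centrality, nonparametric bootstrap edge-weight confidence intervals,
    case-dropping subset bootstrap with the correlation-stability (CS)
    coefficient, bootstrapped difference tests, a Fruchterman-Reingold
    layout, consolidated reporting, cohort filtering for informant-rated
    neuropsychiatric inventories, and a fully specified Ising simulator
    (exact enumeration for small item counts, Gibbs sampling otherwise)
    with presets emulating neuropsychiatric symptom data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
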