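Package: smmbn
Title: Bayesian Network Analysis of Disparities in Severe Maternal Morbidity
Version: 1.0.0
Authors@R:
    person("smmbn", "developers", email = "smmbn@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network toolkit for studying rare delivery
    outcomes and their disparities. Provides directed-acyclic-graph and
    partially-directed-graph types with d-separation, Markov blankets and
    CPDAG conversion; maximum-likelihood conditional probability tables;
    exact enumeration, ancestral sampling and likelihood-weighting
    inference; an eleven-configuration structure-learning roster
    (hill-climbing and tabu search under BIC/AIC, grow-shrink and the
    IAMB family, MMPC-based hybrids) under layering constraints; a
    bootstrap consensus procedure with arc-strength model averaging;
    Distance Weighted Influence node ranking; conditional-probability
    disparity queries with odds ratios; a calibrated synthetic birth-cohort
    generator emulating a ~2%-prevalence severe-maternal-morbidity outcome;
    and an end-to-end reproducible pipeline with CSV/GraphML/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
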