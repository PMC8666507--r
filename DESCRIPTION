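Package: flexconn
Title: Behavioral Flexibility and Resting-State Connectivity Mediation Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking adolescent-alcohol exposure group status
    to behavioral-flexibility deficits through resting-state functional
    connectivity in rodent studies. Scores Pavlovian conditioned-approach
    session logs and attentional set-shift trial sequences (prepotent and
    regressive error taxonomy), cleans ROI time series and computes Pearson /
    Fisher-z connectivity matrices, performs edgewise two-way ANOVA with
    link-based permutation family-wise error control (network-based
    statistics), correlates edges with behavior using beta-distribution
    p-values and FDR correction, builds a principal-component subnetwork
    mediator, and runs counterfactual causal mediation with a Poisson count
    outcome (natural direct/indirect effects, proportion mediated, bootstrap
    inference). A seeded synthetic-data module generates datasets with planted
    connectivity and mediation effects so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
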