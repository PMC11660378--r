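Package: scansoc
Title: Bayesian Multilevel Analysis of Scan-Sampled Animal Social Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying group-, individual- and dyad-level variation
    in scan-sampled social behaviour. Fits a Bayesian hierarchical Bernoulli
    model with multi-membership individual effects, dyad effects, a grooming
    recipient effect and within-day scan-to-scan autocorrelation; decomposes
    variance across levels; estimates dyad-level covariate effects on the odds
    scale; derives posterior social networks with node strength and
    probabilistic clustering coefficients; contrasts groups with highest
    posterior density intervals; and tests for multi-individual interaction
    cliques beyond dyadic rates via posterior-predictive simulation. Includes
    a synthetic scan-data generator with known ground truth so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
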