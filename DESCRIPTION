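Package: nodalyield
Title: Occult Nodal Disease Modeling and Lymph Node Yield Adequacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beta-binomial modeling of occult (residual) lymph-node
    metastasis in papillary thyroid microcarcinoma. Fits the latent
    per-node positivity law by maximum likelihood (plain or
    zero-truncated), computes miss-probability curves as a function of
    the number of nodes examined, corrects observed nodal prevalence
    for false-negative staging, determines the minimum adequate node
    yield at a given confidence, and attaches percentile-bootstrap
    uncertainty and chi-square goodness of fit. A companion survival
    toolkit verifies the prognostic relevance of node yield on
    registry-style cohorts: eligibility filtering, Kaplan-Meier and
    log-rank comparison at a yield cutoff with an elderly subgroup, and
    multivariable Cox proportional-hazards models with restricted cubic
    splines and AIC-based knot selection. Includes seeded generators
    for nodal-pathology and survival cohorts with the assumed
    statistical structure.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
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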