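Package: frailtraj
Title: Longitudinal Claims-Based Frailty Trajectories in Administrative Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying changes in a claims-based frailty index over
    time in administrative (Medicare-like) claims data. Implements rolling
    180-day frailty ascertainment windows and Faurot-style logistic frailty
    scoring, eligibility-driven cohort construction with exact matching of
    noncancer comparators, standardized mortality ratio (SMR) and inverse
    probability of attrition weighting, weighted generalized estimating
    equations with gamma variance, identity link and AR(1) working
    correlation, K-means clustering of longitudinal frailty trajectories with
    a Calinski-Harabasz cluster-count criterion, and logistic modelling of
    nonresilient-trajectory predictors. A calibrated synthetic claims
    generator makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    arrow,
    jsonlite,
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
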