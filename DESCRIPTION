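Package: cardiovpd
Title: Virtual Patient Databases from a 0D-1D Cardiovascular Digital Twin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates synthetic virtual patient databases (VPDs) of the
    human arterial circulation. A one-dimensional pulse-wave solver
    (MacCormack predictor-corrector with method-of-characteristics
    boundary closure) is coupled to lumped-parameter (0D) models of the
    heart, peripheral beds, coronary and pulmonary circulations, with an
    Olufsen elastic wall law. Cohorts of digital twins are sampled by
    scaling a tuned reference patient with stochastic factors, reduced by
    a literature-guided closest-match resampling step, and stratified by
    sex and age through a greedy moment-matching assignment. Eleven
    physiological quantities of interest (six pressure extrema, cardiac
    output, and four diagnostic pulse wave velocities) are extracted per
    patient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
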