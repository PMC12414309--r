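Package: nightvar
Title: Night-to-Night Sleep Variability and the General Factor of Psychopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking adolescent psychopathology to actigraphy-derived
    nightly sleep metrics. Fits a bifactor s-1 measurement model of
    psychopathology (emotion dysregulation as the reference indicator) by
    full-information maximum likelihood, extracts factor scores, and regresses
    person-level means and intraindividual (log residual variance) variability
    of nightly sleep duration, bedtime and waketime on those scores in a
    Bayesian mixed-effects location-scale model estimated by a Gibbs sampler
    with potential-scale-reduction convergence checks. Includes a synthetic
    cohort generator with the same latent structure for offline testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
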