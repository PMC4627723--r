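Package: confbms
Title: Bayesian Model Comparison of Confidence Reports in Two-Interval
    Forced-Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models of decisions and confidence reports in a
    two-interval forced-choice contrast-discrimination task (Difference,
    Max, and Bayes-optimal confidence variables), a quantile-based
    reparametrization of decision and confidence thresholds as response
    probabilities, Monte-Carlo estimation of trial likelihoods, fully
    Bayesian per-subject model evidence via importance sampling with a
    counts-based Dirichlet proposal, and fixed- and random-effects group
    model comparison with exceedance probabilities. Includes a simulator
    of the experimental design for recovery studies and ggplot2 figures
    of theoretical confidence distributions and confidence-region maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
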