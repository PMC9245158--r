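Package: relmsm
Title: Non-Parametric Multi-State Models with Relative Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric estimation for Markov multi-state models in which
    transitions into death states are split into population and excess
    components using external population mortality tables. Provides
    Nelson-Aalen cumulative hazards with Greenwood variances, Aalen-Johansen
    transition probabilities on the extended (split) state space, bootstrap
    and Greenwood variance options, six confidence-interval constructions,
    a competing-risks cohort simulator with known truth obtained by
    numerical integration over the covariate distribution, and an ADEMP
    performance harness (bias, empirical standard error, coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
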