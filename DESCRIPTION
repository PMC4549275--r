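Package: structbayes
Title: Hierarchical Bayesian Structure Learning in Sensorimotor Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of structure learning in Bayesian
    sensorimotor integration. Implements closed-form integration of a
    bivariate Gaussian prior over a visuomotor shift with visual feedback of
    varying reliability, a hierarchical learner with a normal-inverse-Wishart
    hyper-prior over the shift distribution that acquires the correlation
    structure from full-feedback trials, and a bounded-rational actor that
    responds by rejection sampling from its posterior belief. Includes a
    trial-level experiment simulator (four feedback conditions, four
    sessions, multiple training groups), a behavioural analysis pipeline
    (robust bisquare slope fits, sliding-window statistics, no-feedback
    endpoint means and correlations, trial-by-trial carryover measures,
    nonparametric group comparisons), and import/export of per-trial record
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
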