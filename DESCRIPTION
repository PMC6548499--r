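Package: operantmicro
Title: Microstructural Analysis of Operant Reward Seeking and Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for microstructural analysis of timestamped operant
    event logs from rodent lever-press tasks. Classifies lever presses by
    press-contingent food-cup approach (press-approach action chunks vs
    discrete presses), detects noncontingent approach bouts, computes
    peri-event approach-probability histograms, and derives the standard
    assay measures for Pavlovian-to-instrumental transfer (PIT) and
    outcome-devaluation tests, including PIT scores split by press type.
    Includes a statistical layer (square-root transform of proportions,
    paired and one-sample t tests, Pearson correlation, and a Poisson
    log-link mixed-model contract for response counts) and a virtual-rat
    session simulator that generates event logs under random-interval and
    random-ratio schedules with ground-truth generative parameters, so the
    whole pipeline is testable by parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
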