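Package: heatbands
Title: Prenatal Heat Exposure Metrics and Fixed-Effects Birth Outcome Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing prenatal heat-exposure metrics in birth-outcome
    regressions. Constructs five heat metrics from daily weather (temperature-band
    day counts, trimester averages, Excess Heat Factor heatwave counts, combined
    maximum/minimum bands, and Stull wet-bulb bands), fits linear probability
    models of preterm birth with absorbed interacted fixed effects and
    cluster-robust inference, selects a preferred metric by a joint-significance
    screen followed by AIC ranking, and produces counterfactual
    hottest-versus-coolest seasonal predictions with delta-method confidence
    intervals. Includes a synthetic weather and birth-cohort generator with a
    known exposure-to-outcome data-generating process so the whole pipeline can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
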