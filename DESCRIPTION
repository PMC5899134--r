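Package: ribocap
Title: Translation Resource Competition and Expression Burden Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models competition of synthetic constructs for a shared, finite
    ribosome pool using a coarse-grained ribosome-flow (mean-field TASEP)
    description of translation, and turns cell-free lysate capacity-monitor
    measurements into predictions of in vivo expression burden. Provides a
    steady-state solver for multi-species competitive translation, inversion
    of measured normalized capacities into a lumped per-gene synthesis cost
    (gamma), extraction of growth rates and maximal GFP production rates from
    plate-reader kinetics, linear in vitro to in vivo calibration, operon
    burden prediction, decomposition of measured burden into expression and
    metabolic components, and a fully ground-truthed synthetic data generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
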