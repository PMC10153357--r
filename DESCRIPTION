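Package: rtpdosim
Title: Reduced Time Point Dosimetry: Time-Integrated Activity Accuracy and
    Uncertainty Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the accuracy and uncertainty of reduced
    time point estimation of time-integrated activity (TIA) in Lu-177
    DOTATATE internal dosimetry. Provides mono- and biexponential
    time-activity curve models with analytic TIA, AIC-based model
    selection for four-time-point reference fits, closed-form single
    time point estimators (Hanscheid and Madsen), a SPECT measurement
    noise power law fitted from repeat phantom measurements, exhaustive
    enumeration of admissible one-, two- and three-time-point sampling
    schedules, a virtual patient simulator that bootstraps fit types and
    draws curve parameters from truncated lognormal distributions, and
    RMSE/MPE/MAPE error summaries with optimal-schedule search and
    plotting helpers.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
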