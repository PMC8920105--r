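Package: warfinr
Title: Steady-State Warfarin PK-PD Modelling and Dose-INR Back-Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links warfarin maintenance dose to the prothrombin-time
    international normalized ratio (PT-INR) through a steady-state
    pharmacokinetic-pharmacodynamic model, and inverts that model by
    maximum-a-posteriori (MAP) estimation to back-predict individual
    maximum concentration, elimination rate, clearance and volume of
    distribution from routine clinic dose/INR records. Also computes
    standard anticoagulation-quality indices (warfarin sensitivity index,
    Rosendaal time in therapeutic range, log-INR variability, the warfarin
    composite measure and predicted liver weight), cohort-level outlier
    classification, group comparisons and correlations, and ships a
    synthetic-cohort generator so the whole analysis is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
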