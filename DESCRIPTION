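Package: wardmon
Title: Agreement Analysis for Continuous Ward Vital-Sign Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating continuous wearable vital-sign monitors
    against intermittent nurse spot-checks on surgical wards: rule-based
    physiological artifact filtering, data-completeness accounting on a
    5-minute slot grid, time-aligned pairing of nurse and device readings,
    repeated-measures Bland-Altman limits of agreement, Clarke Error Grid
    classification, and per-patient abnormality concordance (Cohen's kappa
    and McNemar's exact or continuity-corrected test). Includes a seeded
    synthetic ward-monitoring generator with ground-truth labels so every
    stage of the pipeline can be tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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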