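Package: snaqr
Title: Brief Food-Group Dietary Analysis for Pregnancy with Relative-Validity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-day food-group serving records (optionally with
    micronutrient supplement use) into estimates of daily energy and five key
    pregnancy nutrients (iron, calcium, folate as dietary folate equivalents,
    iodine and zinc), classifies nutrient adequacy against pregnancy Estimated
    Average Requirement (EAR) and Recommended Dietary Intake (RDI) reference
    values, compares food-group intake against Australian Guide to Healthy
    Eating (AGTHE) pregnancy serving targets, and quantifies inter-method
    agreement between the brief analysis and a full reference nutrient
    analysis using Spearman rank correlation and Cohen kappa. A seeded
    synthetic-cohort generator produces paired brief/reference datasets with
    configurable measurement error for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
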