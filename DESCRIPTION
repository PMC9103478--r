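Package: uastone
Title: Interpretable Additive Neural Classification of Uric Acid Kidney Stones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical risk model distinguishing pure uric acid kidney stones
    from other stone compositions using eight routine variables (sex, age,
    eGFR, urine pH, BMI, diabetes, gout, bacteriuria). Implements a small
    neural additive classifier trained with class-weighted binary
    cross-entropy, ROC analysis with Youden-index cutoff selection and
    Wald/DeLong confidence intervals, an MDRD eGFR calculator, and a
    synthetic-cohort generator that reproduces published class-conditional
    summary statistics for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
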