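Package: ehrisk
Title: Sequence Risk Models and Perturbation-Based Relative Contributions for Longitudinal EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds case/control cohorts from longitudinal electronic health
    record (EHR) event streams, trains sequence risk models (logistic
    regression, recurrent networks, a time-aware LSTM, and a two-level
    attention model) for short-horizon outcome prediction, and ranks
    clinical features by a perturbation-based relative-contribution (RC)
    statistic with Wilcoxon rank-sum testing and false-discovery-rate
    control. Includes a drug-to-protein-target layer for target-level
    pooling and substitution analyses, and a seeded synthetic EHR
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
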