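Package: hivcea
Title: Individual-Level Microsimulation for HIV Treatment-Sequencing
    Cost-Effectiveness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo individual-level state-transition model of
    treatment-experienced, integrase-inhibitor-naive HIV patients moving
    through successive antiretroviral treatment lines. Simulates monthly
    cycles of virologic response, CD4 trajectory, opportunistic
    infections, and mortality over a lifetime horizon, accruing
    discounted costs and quality-adjusted life years under a French
    collective perspective. Provides paired-arm comparison with common
    random numbers (ICER and dominance classification), resistance
    calibration, one-way deterministic sensitivity analysis, structural
    scenario analysis, and drug price sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
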