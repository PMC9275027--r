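Package: oncovalue
Title: ASCO Value Framework and ESMO-MCBS Scoring for Oncology Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores randomized oncology trial evidence with the two major
    value-assessment tools for advanced disease: the ASCO Value Framework
    v2.0 net health benefit (clinical benefit from hazard ratios or response
    rates, a two-arm toxicity score, and bonus points) and the ESMO Magnitude
    of Clinical Benefit Scale v1.1 non-curative forms 2a/2b/2c (threshold
    grading on the lower confidence bound of the hazard ratio and the
    absolute survival gain, with adjustment upgrades). Trial evidence lives
    in a tidy tibble with one row per randomized comparison; scoring verbs
    return tibbles that reproduce the published framework tables. Includes a
    28-day regimen drug-cost model, a seeded synthetic trial generator with a
    patient-level exponential survival simulator and a log-rank one-step
    hazard-ratio estimator, fixtures for six first-line metastatic renal
    cell carcinoma trials, and a command-line interface.
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
    grid,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
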