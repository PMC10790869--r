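Package: gapnirs
Title: Gap-Acceptance Psychometrics and fNIRS Decoding for Driver-Vehicle
    Interaction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of how drivers interact with autonomous versus
    human-driven vehicles at unsignalized intersections. Simulates oncoming
    traffic streams with controlled gap-size structure and Bernoulli driver
    decisions, fits the two-parameter logistic gap-acceptance (psychometric)
    model with bootstrap confidence intervals, generates and preprocesses
    two-wavelength functional near-infrared spectroscopy (fNIRS) recordings
    (channel quality screening, zero-phase band-pass, modified Beer-Lambert
    conversion, decision-phase epoching), decodes the interaction partner from
    multichannel deoxyhemoglobin epochs with PCA-reduced nested cross-validated
    logistic ridge regression, and combines subject-level channel t-maps into
    accuracy-weighted group effect-size (Cohen's d) maps.
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
    glmnet,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
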