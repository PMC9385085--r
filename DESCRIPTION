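Package: tactrain
Title: Simulation and Analysis of Multi-Session Vibrotactile P300
    Brain-Computer Interface Training Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-session training
    studies of a four-choice vibrotactile P300 brain-computer interface
    (BCI). Provides stimulus-schedule generation for oddball calibration
    and copy-task runs, a synthetic event-related-potential (ERP) EEG
    generator with 1/f noise and artifact injection, offline ERP
    preprocessing (band-pass filtering, epoching, baseline correction,
    amplitude-based artifact rejection), stepwise linear discriminant
    analysis (SWLDA) decoding with the N-choice selection rule,
    information-transfer-rate metrics, dual-task impact quantification,
    NASA-TLX workload aggregation, an adaptive two-interval forced-choice
    intensity-discrimination procedure with sigmoid threshold estimation,
    and the repeated-measures statistical battery (Greenhouse-Geisser
    corrected ANOVA, paired t tests with Cohen's d_z, Pearson
    correlations) typically applied to such studies. All user-facing
    functions take data frames and return tibbles so analyses compose
    with the pipe.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
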