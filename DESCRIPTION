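Package: tgpsel
Title: Transgenerational Plasticity and Selection in Split-Clutch Salinity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-generation, full-factorial split-clutch
    acclimation experiments in which parents and offspring are exposed to
    native ("control") or foreign ("treatment") salinities. Provides the
    treatment-design coordinate system, a hierarchical synthetic-data
    generator with time-structured and optionally size-selective mortality,
    log response ratio (lnR) effect-size tables, linear and generalised
    linear mixed models with type-III tests, backward AIC model selection and
    Tukey HSD post hoc contrasts, and an in-silico truncation-selection
    engine that re-runs the effect-size meta-analysis under counterfactual
    mortality scenarios to separate plasticity from selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stats,
    utils,
    MASS,
    lme4,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
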