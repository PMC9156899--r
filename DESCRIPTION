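Package: daypref
Title: Day-Level Dynamics of Risk, Ambiguity and Time Preferences from
    Ecological Momentary Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying day-to-day variation in economic
    decision-making preferences measured with smartphone-based ecological
    momentary assessment (EMA). Generates the monetary lottery (known risk
    and ambiguity) and intertemporal choice trial sets and their incentive
    (bonus-realization) scheme; implements power-utility and hyperbolic
    discounting choice models with logistic (softmax) choice rules; fits
    risk tolerance (alpha), ambiguity tolerance (beta), discount rate
    (kappa) and choice stochasticity (gamma) by per-subject-per-day
    maximum likelihood with BIC comparison of delay conventions;
    decomposes parameter variation into between- and within-person
    components (ICC from random-intercept mixed models) with week-level
    down-sampling; and relates day-level preferences to momentary mood via
    within-person-centered mixed-effects models with Satterthwaite degrees
    of freedom. A synthetic-cohort generator reproduces the statistical
    structure of a two-group (opioid use disorder vs. control) 28-day EMA
    study so the full pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
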