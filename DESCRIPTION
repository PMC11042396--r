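Package: ttsrisk
Title: Flexible Competing-Risks Modelling of Time-to-Surgery Mortality Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Propensity-weighted Fine-Gray competing-risks modelling of
    breast-cancer-specific mortality as a smooth function of continuous time
    from diagnostic biopsy to surgery (TTS). Provides a synthetic
    SEER-Medicare-like cohort generator with a known subdistribution-hazard
    structure, the study eligibility cascade with exclusion bookkeeping,
    covariate-balancing generalized propensity-score weights for the
    continuous log-TTS exposure (stabilized, balance-refined, normalized and
    winsorized), weighted Fine-Gray estimation with B-spline TTS effects,
    robust sandwich covariance and Breslow baseline subdistribution hazard,
    subdistribution hazard-ratio curves with pointwise and Scheffe
    simultaneous confidence bands referenced to TTS = 30 days, weekly
    risk tables, and adjusted cumulative incidence functions at selected
    TTS values for a modal covariate profile.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
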