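# Study-condition truths used across the suite.

# single-stratum HR+/HER2- truth with the published flat-then-exponential
# curve (onset day 42, 10%/week) and the default confounding structure
hrpos_truth <- function() {
  simulation_truth(subtype_probs = c(hrpos_her2neg = 1, her2pos = 0,
                                     tnbc = 0))
}

# null truth: no TTS effect in any subtype and no exposure confounding
null_truth <- function() {
  simulation_truth(
    subtype_probs = c(hrpos_her2neg = 1, her2pos = 0, tnbc = 0),
    tts_curve_params = list(
      hrpos_her2neg = list(shape = "flat_then_exponential", onset_day = 42,
                           weekly_increment = 0),
      her2pos = list(shape = "linear_shr", onset_day = 30,
                     weekly_increment = 0),
      tnbc = list(shape = "linear_shr", onset_day = 30,
                  weekly_increment = 0)),
    tts_confounding_coefs = list())
}

# truth with no covariate effects on either cause and no confounding, so
# the cumulative incidence has the closed form of true_cif() exactly
clean_cif_truth <- function() {
  simulation_truth(
    subtype_probs = c(hrpos_her2neg = 1, her2pos = 0, tnbc = 0),
    tts_confounding_coefs = list(),
    covariate_coefs_cause1 = list())
}

# HR+ truth with a single strong confounder (SEER stage) that affects both
# TTS and breast-cancer mortality but is NOT in the Fine-Gray adjustment
# set, so the unweighted curve is biased and only the propensity weights
# can remove the bias
confounded_truth <- function() {
  conf <- default_tts_confounding()
  conf$stage <- c(regional_nodes = 0.30)
  c1 <- default_cause1_coefs()
  c1$stage <- c(regional_nodes = 0.80)
  simulation_truth(subtype_probs = c(hrpos_her2neg = 1, her2pos = 0,
                                     tnbc = 0),
                   tts_confounding_coefs = conf,
                   covariate_coefs_cause1 = c1)
}

# generate + screen one stratum and fit the full weighting + Fine-Gray
# pipeline; returns pieces used by the simulation-based tests
fit_stratum <- function(truth, n, seed, weighted = TRUE,
                        subtype = "hrpos_her2neg") {
  cohort <- apply_exclusions(generate_cohort(truth, n, seed = seed))$cohort
  cohort <- cohort[cohort$subtype == subtype, , drop = FALSE]
  wp <- if (weighted) {
    weight_pipeline(cohort, gps_covariates(subtype))
  } else {
    NULL
  }
  fit <- fit_finegray(cohort, adjust = adjust_covariates(subtype),
                      ipw = if (weighted) wp$weights else NULL)
  list(cohort = cohort, wp = wp, fit = fit)
}

# a small screened cohort used by quick structural tests
quick_cohort <- function(n = 4000, seed = 123) {
  apply_exclusions(generate_cohort(simulation_truth(), n, seed = seed))$cohort
}
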