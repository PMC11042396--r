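test_that("GPS regression recovers the generator's log-TTS model", {
  truth <- simulation_truth()
  # raw cohort (only tts > 0) so the TTS >= 120 screening rule does not
  # truncate the long-TTS tail and attenuate the coefficients
  cohort <- generate_cohort(truth, 20000, seed = 31)
  cohort <- cohort[cohort$tts_days > 0, ]
  st <- cohort[cohort$subtype == "hrpos_her2neg", ]
  m <- fit_gps(st, gps_covariates("hrpos_her2neg"))
  # residual SD near the generator's sigma (rounding to integer days adds
  # a little extra spread at short TTS)
  expect_equal(m$sigma, truth$tts_sigma, tolerance = 0.05)
  # a strong known coefficient: mastectomy with reconstruction
  bhat <- m$coefs[["surgery_typemastectomy_recon"]]
  expect_equal(bhat, 0.44, tolerance = 0.05 / 0.44)
  # null model under zero confounding: coefficients near zero
  cn <- apply_exclusions(generate_cohort(
    simulation_truth(tts_confounding_coefs = list()), 20000, seed = 8))$cohort
  cn <- cn[cn$subtype == "hrpos_her2neg", ]
  m0 <- fit_gps(cn, gps_covariates("hrpos_her2neg"))
  se_rough <- m0$sigma / sqrt(nrow(cn) * 0.05)  # crudest indicator SE scale
  expect_lt(max(abs(m0$coefs[-1L])), 3 * se_rough)
})

test_that("stabilized weights equal the explicit density ratio", {
  cohort <- quick_cohort(2000)
  st <- cohort[cohort$subtype == "hrpos_her2neg", ]
  m <- fit_gps(st, c("radiation", "cci"))
  w <- stabilized_weights(m, st)
  expect_true(all(w$raw > 0))
  # hand computation for the first record
  s <- log(st$tts_days[1])
  Z <- ttsrisk:::.covariate_design(st, c("radiation", "cci"))
  mu1 <- drop(c(1, Z[1, ]) %*% m$coefs)
  expect_equal(w$raw[1],
               dnorm(s, m$marginal_mean, m$marginal_sd) /
                 dnorm(s, mu1, m$sigma))
  # conditional model with no covariate signal ~ marginal: weights near 1
  expect_equal(mean(w$raw), 1, tolerance = 0.05)
})

test_that("balance refinement zeroes the weighted cross-moments", {
  cohort <- quick_cohort(8000, seed = 77)
  st <- cohort[cohort$subtype == "hrpos_her2neg", ]
  covs <- gps_covariates("hrpos_her2neg")
  m <- fit_gps(st, covs)
  mb <- balance_refine(m, st)
  expect_true(mb$balanced)
  w <- stabilized_weights(mb, st)$raw
  s <- log(st$tts_days)
  s_std <- (s - mb$marginal_mean) / mb$marginal_sd
  Z <- scale(ttsrisk:::.covariate_design(st, covs))
  moments <- crossprod(cbind(1, Z), w * s_std) / nrow(st)
  expect_lt(max(abs(moments)), 1e-6)
  # raw refined weights give (numerically) zero weighted correlations
  rep <- balance_report(st, w, covs)
  expect_lt(max(abs(rep$post_cor)), 1e-6)
  expect_lt(max(abs(rep$post_cor)), max(abs(rep$pre_cor)))
})

test_that("refinement is a no-op on already-balanced data", {
  cn <- apply_exclusions(generate_cohort(
    simulation_truth(tts_confounding_coefs = list()), 15000, seed = 9))$cohort
  cn <- cn[cn$subtype == "hrpos_her2neg", ]
  m <- fit_gps(cn, c("race_eth", "surgery_type"))
  mb <- balance_refine(m, cn)
  # ML fit is already near the balancing solution
  expect_lt(max(abs(mb$coefs - m$coefs)), 0.02)
})

test_that("normalization and winsorization follow the declared arithmetic", {
  # constant weights map to all ones
  w <- normalize_winsorize(rep(2, 50))
  expect_equal(w$final, rep(1, 50))
  # weights 1..100 with a 95% cap: direct oracle
  x <- as.numeric(1:100)
  w2 <- normalize_winsorize(x, cap_percentile = 95)
  cap <- unname(quantile(x, 0.95, type = 7))
  capped <- pmin(x, cap)
  expect_equal(attr(w2, "winsor_cap"), cap)
  expect_equal(w2$final, capped / mean(capped))
  expect_equal(mean(w2$final), 1, tolerance = 1e-12)
  expect_lte(max(w2$capped), cap)
  # only the upper tail is touched by default
  expect_equal(w2$capped[x <= cap], x[x <= cap])
  # two-sided option caps the lower tail too
  w3 <- normalize_winsorize(x, cap_percentile = 95, two_sided = TRUE)
  lo <- unname(quantile(x, 0.05, type = 7))
  expect_equal(min(w3$capped), lo)
  expect_error(normalize_winsorize(x, cap_percentile = 40),
               "cap_percentile")
  expect_error(normalize_winsorize(c(1, -1)), "positive")
})

test_that("balance report reduces to the unweighted report at weight 1", {
  cohort <- quick_cohort(3000)
  st <- cohort[cohort$subtype == "hrpos_her2neg", ]
  covs <- gps_covariates("hrpos_her2neg")
  rep1 <- balance_report(st, rep(1, nrow(st)), covs)
  expect_equal(rep1$post_cor, rep1$pre_cor, tolerance = 1e-12)
  expect_true(all(abs(rep1$pre_cor) <= 1, na.rm = TRUE))
})

test_that("weight pipeline output satisfies the weight-set invariants", {
  cohort <- quick_cohort(6000, seed = 55)
  st <- cohort[cohort$subtype == "hrpos_her2neg", ]
  wp <- weight_pipeline(st, gps_covariates("hrpos_her2neg"))
  w <- wp$weights
  expect_true(all(w$final > 0))
  expect_lt(abs(mean(w$final) - 1), 1e-9)
  expect_lte(max(w$capped), attr(w, "winsor_cap"))
  expect_equal(attr(w, "cap_percentile"), 95)
})
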