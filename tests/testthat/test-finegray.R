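test_that("spline basis satisfies its structural invariants", {
  b <- build_spline_basis(c(10, 20, 30, 40, 60, 100), degree = 3,
                          interior_knots = c(24, 36))
  expect_equal(b$n_basis, 5L)  # 2 interior knots + degree 3
  # partition of unity of the full basis at interior and boundary days
  B <- spline_design(b, c(8, 30, 60, 119), full = TRUE)
  expect_equal(rowSums(B), rep(1, 4))
  expect_true(all(B >= 0))
  # model basis drops one column
  expect_equal(ncol(spline_design(b, 30)), 5L)
  # deterministic evaluation
  expect_identical(spline_design(b, c(15, 75)), spline_design(b, c(15, 75)))
  # default knots at the 33rd/67th percentiles of observed TTS
  tts <- quick_cohort(2000)$tts_days
  b2 <- build_spline_basis(tts)
  expect_equal(b2$interior_knots,
               unname(quantile(tts, c(0.33, 0.67), type = 7)))
  expect_error(build_spline_basis(tts, interior_knots = c(5, 30)),
               "strictly inside")
  expect_error(spline_design(b, 130), "boundary")
})

test_that("risk-set weights reproduce a hand-worked Kaplan-Meier example", {
  # five subjects: cause-1 events at t=1 and t=4, a cause-2 death at t=2,
  # a censoring at t=3, and one follow-up to t=5
  cohort <- data.frame(surv_years = c(1, 2, 3, 4, 5),
                       event_type = c(1L, 2L, 0L, 1L, 0L))
  rw <- finegray_riskset_weights(cohort)
  expect_equal(rw$event_times, c(1, 4))
  # censoring KM: one censoring among 3 at risk at t=3 -> G = 2/3 after 3;
  # the final censoring at t=5 (last subject at risk) drops G to 0
  expect_equal(rw$G$surv, c(2 / 3, 0))
  # at t=1 everyone is at risk with weight 1
  expect_equal(rw$omega(1), rep(1, 5))
  # at t=4: subject 2 (cause 2 at t=2) carries G(4-)/G(2-) = (2/3)/1
  expect_equal(rw$omega(4), c(0, 2 / 3, 0, 1, 1))
  # weights of prior cause-2 subjects never increase over time
  expect_true(all(diff(c(rw$omega(2.5)[2], rw$omega(3.5)[2],
                         rw$omega(4.5)[2])) <= 0))
  # without censoring G is identically 1 and cause-2 subjects keep weight 1
  noc <- data.frame(surv_years = c(1, 2, 4), event_type = c(1L, 2L, 1L))
  rw2 <- finegray_riskset_weights(noc)
  expect_equal(rw2$omega(3), c(0, 1, 1))
})

test_that("partial likelihood matches the brute-force oracle on micro data", {
  set.seed(404)
  for (r in 1:25) {
    d <- random_micro_data()
    beta <- rnorm(2, 0, 0.7)
    mine <- finegray_loglik(d$time, d$status, d$X, d$ipw, beta)
    ref <- fg_brute(d$time, d$status, d$X, d$ipw, beta)
    expect_equal(mine$loglik, ref$loglik, tolerance = 1e-10)
    expect_equal(mine$score, unname(ref$score), tolerance = 1e-10)
    expect_equal(unclass(mine$info), unclass(ref$info), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("fit reduces to Cox regression without competing events", {
  set.seed(77)
  n <- 200
  cohort <- quick_cohort(2500, seed = 66)
  cohort <- cohort[cohort$subtype == "hrpos_her2neg", ][1:n, ]
  cohort$surv_years <- rexp(n)
  cohort$event_type <- sample(c(0L, 1L), n, TRUE, c(0.4, 0.6))
  basis <- build_spline_basis(cohort$tts_days)
  fit <- fit_finegray(cohort, basis = basis, adjust = c("radiation", "cci"))
  X <- cbind(spline_design(basis, cohort$tts_days),
             ttsrisk:::.covariate_design(cohort, c("radiation", "cci")))
  cox <- survival::coxph(
    survival::Surv(cohort$surv_years, cohort$event_type) ~ X,
    ties = "breslow",
    control = survival::coxph.control(eps = 1e-11, iter.max = 100))
  expect_lt(max(abs(fit$beta - coef(cox))), 1e-6)
})

test_that("estimates agree with survival::finegray on expanded data", {
  set.seed(2024)
  n <- 400
  time <- rexp(n)
  status <- sample(0:2, n, TRUE, c(0.35, 0.35, 0.30))
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  df <- data.frame(id = seq_len(n), time,
                   ev = factor(status, 0:2, c("cens", "bc", "other")),
                   x1 = X[, 1], x2 = X[, 2])
  fgd <- survival::finegray(survival::Surv(time, ev) ~ ., data = df,
                            etype = "bc", id = id)
  cox <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ x1 + x2, data = fgd,
    weights = fgwt, id = id, robust = TRUE, ties = "breslow",
    control = survival::coxph.control(eps = 1e-11, iter.max = 100))
  beta <- c(0, 0)
  for (i in 1:40) {
    e <- finegray_loglik(time, status, X, rep(1, n), beta)
    beta <- beta + solve(e$info, e$score)
  }
  expect_lt(max(abs(beta - coef(cox))), 1e-8)
  # robust sandwich agrees with the clustered jackknife of coxph
  km <- ttsrisk:::.censoring_km(time, status)
  ord <- order(time, status)
  tev <- sort(unique(time[status == 1]))
  core <- ttsrisk:::fg_core(X[ord, ], time[ord], as.integer(status[ord]),
                            rep(1, n), tev, km$Gminus(tev),
                            ifelse(status[ord] == 2, km$Gminus(time[ord]), 1),
                            beta, TRUE)
  Ii <- solve(core$info)
  Sig <- Ii %*% crossprod(core$resid) %*% Ii
  expect_equal(sqrt(diag(Sig)), sqrt(diag(vcov(cox))), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("rescaling all IPW leaves the coefficients unchanged", {
  res <- fit_stratum(hrpos_truth(), 4000, seed = 44)
  w <- res$wp$weights$final
  fit2 <- fit_finegray(res$cohort, basis = res$fit$basis, ipw = 7.3 * w)
  fit1 <- fit_finegray(res$cohort, basis = res$fit$basis, ipw = w)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
})

test_that("baseline hazard and CIF transform respect their invariants", {
  res <- fit_stratum(hrpos_truth(), 5000, seed = 45)
  fit <- res$fit
  expect_true(all(diff(fit$baseline$cumhaz) >= 0))
  expect_equal(min(fit$baseline$cumhaz), fit$baseline$haz[1])
  b0 <- baseline_cif(fit, 0)
  expect_equal(b0$cif, 1 - exp(-b0$cumhaz))
  expect_equal(b0$cif[1], 0)
  expect_true(all(b0$cif >= 0 & b0$cif < 1))
  expect_true(all(diff(b0$cif) >= 0))
  # eta -> -Inf sends the CIF to zero pointwise
  expect_lt(max(baseline_cif(fit, -30)$cif), 1e-10)
  # robust covariance is symmetric positive semi-definite
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  cohort <- quick_cohort(800, seed = 47)
  no_ev <- cohort
  no_ev$event_type[no_ev$event_type == 1L] <- 0L
  expect_error(fit_finegray(no_ev), "no breast-cancer death")
  dup <- cohort
  dup$chemo <- dup$radiation  # force collinearity
  expect_error(fit_finegray(dup, adjust = c("radiation", "chemo")),
               "collinear")
})

test_that("pseudo-LR spline test is bounded and coherent with its fits", {
  res <- fit_stratum(hrpos_truth(), 6000, seed = 48)
  lr <- spline_lr_test(res$cohort, ipw = res$wp$weights)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 5L)
  expect_equal(lr$statistic,
               2 * (lr$fit_full$loglik - lr$fit_null$loglik))
  expect_equal(length(lr$fit_null$spline_cols), 0L)
  # nesting: the full model can never have lower maximized loglik
  expect_gte(lr$fit_full$loglik, lr$fit_null$loglik)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
})
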