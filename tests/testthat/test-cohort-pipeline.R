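# a clean screened record template for planting targeted violations
clean_raw <- function(n = 1, seed = 42) {
  co <- generate_cohort(simulation_truth(planted_flag_rate = 0), 5 * n + 50,
                        seed = seed)
  co <- co[co$tts_days >= 8 & co$tts_days <= 119, ]
  attr(co, "latent") <- NULL
  head(co, n)
}

test_that("exclusion cascade applies the published rules in order", {
  base <- clean_raw(3)
  # surgery within 7 days of biopsy -> rule 4, even though flags are clean
  r <- base[1, ]
  r$tts_days <- 5L
  out <- apply_exclusions(rbind(r, base[2:3, ]))
  expect_equal(attr(out$log, "n_retained"), 2L)
  expect_equal(out$log$n_excluded[out$log$rule == "tts_lt_8"], 1L)
  # TTS >= 120 excluded; 119 retained
  r2 <- base[1:2, ]
  r2$tts_days <- c(120L, 119L)
  out2 <- apply_exclusions(r2)
  expect_equal(out2$cohort$tts_days, 119L)
  # first-matching rule wins for multi-reason records
  r3 <- base[1, ]
  r3$flag_nonlocoregional <- TRUE
  r3$flag_missing_info <- TRUE
  r3$tts_days <- 3L
  out3 <- apply_exclusions(r3)
  expect_equal(out3$log$n_excluded[out3$log$rule == "nonlocoregional"], 1L)
  expect_equal(sum(out3$log$n_excluded), 1L)
  # a clean record with an event at 3 years is retained
  r4 <- base[1, ]
  r4$tts_days <- 30L
  r4$surv_years <- 3
  r4$event_type <- 1L
  expect_equal(attr(apply_exclusions(r4)$log, "n_retained"), 1L)
})

test_that("planted single-rule violations are counted exactly", {
  base <- clean_raw(200, seed = 7)
  rules <- c("flag_nonlocoregional", "flag_prior_cancer",
             "flag_nondefinitive_surgery", "tts_lt_8", "tts_ge_120",
             "flag_death_lt_1yr", "flag_followup_lt_tts",
             "flag_missing_info")
  plant <- rep(c(4L, 3L, 3L, 4L, 3L, 3L, 2L, 3L), 1)  # 25 violations
  idx <- 1L
  for (k in seq_along(rules)) {
    rows <- idx:(idx + plant[k] - 1L)
    if (rules[k] == "tts_lt_8") {
      base$tts_days[rows] <- 4L
    } else if (rules[k] == "tts_ge_120") {
      base$tts_days[rows] <- 150L
    } else {
      base[[rules[k]]][rows] <- TRUE
    }
    idx <- idx + plant[k]
  }
  out <- apply_exclusions(base)
  expect_equal(attr(out$log, "n_input"), 200L)
  expect_equal(attr(out$log, "n_retained"), 175L)
  expect_equal(out$log$n_excluded, plant)
  # bookkeeping identity
  expect_equal(attr(out$log, "n_input") - sum(out$log$n_excluded),
               attr(out$log, "n_retained"))
})

test_that("exclusions are idempotent and bound retained TTS to [8, 119]", {
  raw <- generate_cohort(simulation_truth(), 5000, seed = 3)
  once <- apply_exclusions(raw)
  twice <- apply_exclusions(once$cohort)
  expect_identical(once$cohort, twice$cohort)
  expect_equal(sum(twice$log$n_excluded), 0L)
  expect_gte(min(once$cohort$tts_days), 8L)
  expect_lte(max(once$cohort$tts_days), 119L)
  # empty input is an empty cohort with a zeroed log, not an error
  empty <- apply_exclusions(raw[0, ])
  expect_equal(attr(empty$log, "n_retained"), 0L)
  expect_equal(sum(empty$log$n_excluded), 0L)
})

test_that("TTS summary reproduces quantiles and percentages", {
  cohort <- quick_cohort(3000)
  smry <- summarize_tts(cohort)
  expect_named(smry, c("subtype", "covariate", "level", "n", "percent",
                       "median", "q1", "q3"))
  # constant-TTS stratum: all quantiles equal the constant
  const <- cohort
  const$tts_days <- 29L
  s2 <- summarize_tts(const)
  expect_true(all(s2$median[s2$n > 0] == 29))
  expect_true(all(s2$q1[s2$n > 0] == 29 & s2$q3[s2$n > 0] == 29))
  # planted stratum {20,22,28,36,44}: type-7 interpolation oracle
  pl <- clean_raw(5, seed = 11)
  pl$tts_days <- c(20L, 22L, 28L, 36L, 44L)
  pl$subtype <- factor("tnbc", levels = cohort_levels()$subtype)
  pl$hr_status <- factor("neg", levels = cohort_levels()$hr_status)
  s3 <- summarize_tts(pl)
  row <- s3[s3$subtype == "tnbc" & s3$covariate == "all", ]
  expect_equal(row$median, 28)
  expect_equal(row$q1, unname(quantile(c(20, 22, 28, 36, 44), 0.25)))
  expect_equal(row$q3, unname(quantile(c(20, 22, 28, 36, 44), 0.75)))
  # within-covariate percents sum to 100
  sub <- smry[smry$subtype == "hrpos_her2neg" & smry$covariate == "age_group", ]
  expect_equal(sum(sub$percent), 100, tolerance = 1e-9)
  # quartile ordering invariant
  ok <- smry$n > 0
  expect_true(all(smry$q1[ok] <= smry$median[ok] &
                  smry$median[ok] <= smry$q3[ok]))
})

test_that("modal profile matches independent counting and breaks ties", {
  cohort <- quick_cohort(3000)
  prof <- modal_profile(cohort, "hrpos_her2neg")
  for (cov in names(prof)) {
    tab <- table(cohort[[cov]][cohort$subtype == "hrpos_her2neg"])
    expect_equal(unname(prof[[cov]]), names(tab)[which.max(tab)])
  }
  # exact tie on chemo -> first declared level, tie recorded
  tie <- clean_raw(4, seed = 5)
  tie$subtype <- factor("her2pos", levels = cohort_levels()$subtype)
  tie$chemo <- factor(c("no", "no", "yes", "yes"),
                      levels = cohort_levels()$chemo)
  p2 <- modal_profile(tie, "her2pos", covariates = "chemo")
  expect_equal(unname(p2[["chemo"]]), "no")
  expect_equal(attr(p2, "ties"), "chemo")
  expect_error(modal_profile(cohort[0, ], "tnbc"), "empty stratum")
})
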