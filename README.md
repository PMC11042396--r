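# ttsrisk

Flexible, propensity-weighted competing-risks modelling of how
breast-cancer-specific mortality (BCSM) depends on continuous **time to
surgery** (TTS — days from diagnostic biopsy to definitive surgery), by
tumour subtype (HR+/HER2−, HER2+, triple-negative).

The package is aimed at cancer-outcomes researchers who want daily-resolution
risk trajectories instead of coarse TTS bins. Its core is a weighted
**Fine–Gray subdistribution hazard model** with a B-spline TTS effect:

* subdistribution hazard `λ₁(t | x) = λ₁₀(t) · exp{ s(TTS)ᵀβₛ + xᵀβₐ }`,
  where `s(·)` is a cubic B-spline on the retained range [8, 119] days and
  `x` holds adjuvant radiation, chemo/targeted therapy, comorbidity (and HR
  status within HER2+);
* reported effects are contrasts against TTS = 30 days,
  `sHR(t) = exp{(s(t) − s(30))ᵀβ̂ₛ}`, with pointwise 95% intervals and
  **Scheffé simultaneous bands** using the multiplier `√χ²₍d,0.95₎`
  (d = spline dimension) — a day is "significant" only if the simultaneous
  band excludes 1;
* confounding between TTS and patient characteristics is removed by
  stabilized **covariate-balancing generalized propensity score** weights
  for log-TTS (ML fit, exact balancing refinement, 95th-percentile
  winsorization, mean-1 normalization);
* adjusted cumulative incidence
  `F₁(t | η) = 1 − exp{−Λ̂₁₀(t) e^η}` is reported at TTS ∈ {30, 60, 90, 120}
  for the stratum's modal covariate profile, with optional bootstrap
  intervals.

Because the motivating SEER-Medicare data is access-restricted, the package
includes a first-class **synthetic cohort generator** with known true
sHR(TTS) curves (flat-then-exponential for HR+/HER2−, linear for HER2+ and
triple-negative), a covariate structure matching the published cohort summaries, exposure confounding,
competing other-cause mortality and administrative censoring — so every
pipeline stage is validated by parameter recovery. A licensed user can feed
a real extract through the same CSV schema via `run_config(cohort_csv=)`.

## Worked example

```r
library(ttsrisk)
res <- run_pipeline(run_config(seed = 1, n = 46600, outdir = "ttsrisk_run"))

wk <- res$subtypes$hrpos_her2neg$weekly
wk[wk$day %in% c(42, 56, 63, 77, 91, 105, 119),
   c("day", "shr_fmt", "ci_fmt", "significant")]
#>  day shr_fmt       ci_fmt significant
#>   42    1.00  (0.79-1.26)       FALSE
#>   56    1.09  (0.80-1.48)       FALSE
#>   63    1.17  (0.83-1.65)       FALSE
#>   77    1.43  (0.91-2.25)       FALSE
#>   91    1.84  (1.09-3.10)        TRUE
#>  105    2.41  (1.12-5.17)        TRUE
#>  119    3.18 (0.54-18.69)       FALSE
```

This simulates a raw cohort of 46,600 (≈34,000 retained after the
eligibility cascade; ≈28,000 HR+/HER2−, ~3.3% breast-cancer deaths),
estimates balancing weights per stratum, fits the weighted spline Fine–Gray
model, and prints the weekly risk table: the sHR is flat near 1 through day
~42 and then accelerates — 1.84 (simultaneous 95% CI 1.09–3.10) at day 91 —
with the simultaneous band excluding 1 in the late-TTS region; at day 119
the point estimate keeps rising but the band balloons because few patients
wait that long (read tails only together with their bands). The adjusted
5-year cumulative incidence at the modal profile rises from 3.7% at TTS = 30
to 11.3% at TTS = 120 in the same run
(`res$subtypes$hrpos_her2neg$cif$table`). The smaller HER2+ and
triple-negative strata show the expected slower/linear growth with wide,
largely non-significant bands.

Key functions if you want the stages individually: `generate_cohort()`,
`apply_exclusions()`, `summarize_tts()`, `weight_pipeline()`
(= `fit_gps()` + `balance_refine()` + `stabilized_weights()` +
`normalize_winsorize()`), `fit_finegray()`, `shr_curve()`,
`weekly_table()`, `adjusted_cif()`, `spline_lr_test()`. A thin CLI
(`inst/scripts/ttsrisk`, subcommands `simulate … run-all`) wraps the same
functions. See the vignette `vignettes/tts-competing-risks.Rmd` for the
model, the generator's assumptions, and known limitations.

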