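#' Subdistribution hazard-ratio curve with simultaneous bands
#'
#' Evaluates `sHR(t) = exp((s(t) - s(reference))' beta_spline)` on a TTS
#' grid with 95\% pointwise intervals (normal quantile) and Scheffe
#' simultaneous intervals using the multiplier `sqrt(qchisq(level, d))`
#' with d the spline-block dimension -- valid jointly for every contrast in
#' the spline subspace, hence for the whole curve.  A grid day is flagged
#' significant when the simultaneous interval excludes sHR = 1.
#'
#' @param fit A converged [fit_finegray()] object.
#' @param grid TTS days to evaluate (default: every integer day across the
#'   basis boundary range).
#' @param reference_day Reference TTS (default 30 days).
#' @param level Confidence level (default 0.95).
#' @return Object of class `shr_curve`: data frame `(day, log_shr, se,
#'   shr, lo_pt, hi_pt, lo_sim, hi_sim, significant)` with attributes
#'   `reference_day` and `scheffe_df`.
#' @export
shr_curve <- function(fit, grid = NULL, reference_day = 30, level = 0.95) {
  stopifnot(inherits(fit, "finegray_fit"), fit$converged)
  bk <- fit$basis$boundary_knots
  if (is.null(grid)) grid <- seq(ceiling(bk[1]), floor(bk[2]))
  if (any(grid < bk[1] | grid > bk[2])) {
    stop("grid extends outside the basis boundary [", bk[1], ", ", bk[2],
         "]", call. = FALSE)
  }
  if (reference_day < bk[1] || reference_day > bk[2]) {
    stop("reference_day outside the basis boundary", call. = FALSE)
  }
  idx <- fit$spline_cols
  d <- length(idx)
  Sg <- spline_design(fit$basis, grid)
  Sr <- spline_design(fit$basis, reference_day)
  Cs <- sweep(Sg, 2L, drop(Sr))              # spline contrast s(t) - s(ref)
  C <- matrix(0, nrow(Cs), length(fit$beta))
  C[, idx] <- Cs
  est <- drop(C %*% fit$beta)
  se <- sqrt(pmax(rowSums((C %*% fit$Sigma) * C), 0))
  z_pt <- qnorm(1 - (1 - level) / 2)
  z_sim <- sqrt(qchisq(level, df = d))
  lo_sim <- exp(est - z_sim * se)
  hi_sim <- exp(est + z_sim * se)
  structure(data.frame(
    day = grid, log_shr = est, se = se, shr = exp(est),
    lo_pt = exp(est - z_pt * se), hi_pt = exp(est + z_pt * se),
    lo_sim = lo_sim, hi_sim = hi_sim,
    significant = lo_sim > 1 | hi_sim < 1),
    reference_day = reference_day, scheffe_df = d, level = level,
    class = c("shr_curve", "data.frame"))
}

#' Weekly risk table
#'
#' Extracts the curve at weekly TTS points 14, 21, ..., 119 days and
#' formats sHR and simultaneous interval to two decimals.
#'
#' @param curve An [shr_curve()] object whose grid covers days 14--119.
#' @return Data frame `(day, shr, lo_sim, hi_sim, significant, shr_fmt,
#'   ci_fmt)`.
#' @export
weekly_table <- function(curve) {
  stopifnot(inherits(curve, "shr_curve"))
  days <- seq(14L, 119L, by = 7L)
  if (!all(days %in% curve$day)) {
    stop("curve grid must cover weekly days 14..119", call. = FALSE)
  }
  rows <- curve[match(days, curve$day),
                c("day", "shr", "lo_sim", "hi_sim", "significant")]
  rows$shr_fmt <- sprintf("%.2f", rows$shr)
  rows$ci_fmt <- sprintf("(%.2f-%.2f)", rows$lo_sim, rows$hi_sim)
  rownames(rows) <- NULL
  rows
}

# Build the adjustment design row for a covariate profile.
.profile_row <- function(fit, profile) {
  if (!length(fit$adjust)) return(numeric(0))
  profile <- unlist(profile)
  miss <- setdiff(fit$adjust, names(profile))
  if (length(miss)) {
    stop("profile missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- as.data.frame(lapply(fit$adjust, function(a) {
    lv <- fit$adjust_levels[[a]]
    val <- as.character(profile[[a]])
    if (!val %in% lv) {
      stop("profile level '", val, "' not a level of ", a, call. = FALSE)
    }
    factor(val, levels = lv)
  }), stringsAsFactors = FALSE)
  names(dat) <- fit$adjust
  mm <- model.matrix(
    as.formula(paste("~", paste(fit$adjust, collapse = "+"))), dat)
  row <- drop(mm)[-1L]
  if (!identical(names(row), fit$adjust_colnames)) {
    stop("profile design does not align with the fitted adjustment block",
         call. = FALSE)
  }
  row
}

# step-function lookup of a cumulative curve at a horizon
.step_at <- function(time, value, t) {
  idx <- findInterval(t, time)
  ifelse(idx == 0, 0, value[pmax(idx, 1L)])
}

#' Adjusted cumulative incidence at selected TTS values
#'
#' Conditional on a covariate profile (typically the [modal_profile()] of
#' the stratum), computes the model-based cumulative incidence of
#' breast-cancer death over follow-up for each requested TTS value:
#' `eta(tts) = s(tts)' beta_spline + profile' beta_adj`, then
#' `F1(t) = 1 - exp(-Lambda10(t) exp(eta))`.  TTS values outside the basis
#' boundary (e.g. day 120 against a basis ending at 119) are clamped to
#' the boundary.  Uncertainty, when requested, is a percentile bootstrap
#' over cohort resamples with full re-fitting via `refit_fun`;
#' non-converging replicates are dropped and counted, and more than 20\%
#' drops is an error.
#'
#' @param fit A converged [fit_finegray()] object.
#' @param profile Named covariate levels for the adjustment block.
#' @param tts_values TTS days (default `c(30, 60, 90, 120)`).
#' @param horizons Reporting horizons in years (default `c(5, 8)`).
#' @param bootstrap_reps Bootstrap replicates (0 = point estimates only).
#' @param seed Seed for the bootstrap resampling.
#' @param cohort Cohort to resample (required when `bootstrap_reps > 0`).
#' @param refit_fun Function `cohort -> finegray_fit` reproducing the full
#'   estimation pipeline on a resampled cohort (required when
#'   `bootstrap_reps > 0`).
#' @return Object of class `cif_estimate`: `table` (one row per
#'   tts x horizon with `cif` and bootstrap `lo`/`hi`), `curves` (full
#'   step curves per TTS value), `profile`, and bootstrap bookkeeping.
#' @export
adjusted_cif <- function(fit, profile, tts_values = c(30, 60, 90, 120),
                         horizons = c(5, 8), bootstrap_reps = 0,
                         seed = 1L, cohort = NULL, refit_fun = NULL) {
  stopifnot(inherits(fit, "finegray_fit"), fit$converged)
  bk <- fit$basis$boundary_knots
  tts_used <- pmin(pmax(tts_values, bk[1]), bk[2])

  eta_of <- function(f, tts) {
    s <- spline_design(f$basis, tts)
    pr <- .profile_row(f, profile)
    adj <- if (length(pr)) sum(pr * f$beta[-f$spline_cols]) else 0
    drop(s %*% f$beta[f$spline_cols]) + adj
  }
  eta <- eta_of(fit, tts_used)
  curves <- lapply(seq_along(tts_used), function(j) {
    cbind(baseline_cif(fit, eta[j]), tts = tts_values[j])
  })
  tab <- expand.grid(tts = tts_values, horizon = horizons,
                     KEEP.OUT.ATTRS = FALSE)
  tab$cif <- vapply(seq_len(nrow(tab)), function(r) {
    j <- match(tab$tts[r], tts_values)
    .step_at(curves[[j]]$time, curves[[j]]$cif, tab$horizon[r])
  }, numeric(1L))
  tab$lo <- tab$hi <- NA_real_
  dropped <- 0L

  if (bootstrap_reps > 0) {
    if (is.null(cohort) || is.null(refit_fun)) {
      stop("bootstrap requires `cohort` and `refit_fun`", call. = FALSE)
    }
    boot <- matrix(NA_real_, bootstrap_reps, nrow(tab))
    .with_seed(seed, {
      for (b in seq_len(bootstrap_reps)) {
        idx <- sample.int(nrow(cohort), replace = TRUE)
        fb <- tryCatch(refit_fun(cohort[idx, , drop = FALSE]),
                       error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fb)) next
        eb <- eta_of(fb, pmin(pmax(tts_values, bk[1]), bk[2]))
        for (r in seq_len(nrow(tab))) {
          j <- match(tab$tts[r], tts_values)
          cb <- baseline_cif(fb, eb[j])
          boot[b, r] <- .step_at(cb$time, cb$cif, tab$horizon[r])
        }
      }
    })
    ok <- rowSums(is.na(boot)) == 0
    dropped <- sum(!ok)
    if (dropped > 0.2 * bootstrap_reps) {
      stop("more than 20% of bootstrap replicates failed to converge (",
           dropped, "/", bootstrap_reps, ")", call. = FALSE)
    }
    qs <- apply(boot[ok, , drop = FALSE], 2L, quantile,
                probs = c(0.025, 0.975), type = 7)
    tab$lo <- qs[1L, ]
    tab$hi <- qs[2L, ]
  }
  structure(list(profile = profile, tts_values = tts_values,
                 horizons = horizons, table = tab, curves = curves,
                 bootstrap_reps = bootstrap_reps, dropped = dropped),
            class = "cif_estimate")
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat("Adjusted cumulative incidence (profile:",
      paste(names(unlist(x$profile)), unlist(x$profile), sep = "=",
            collapse = ", "), ")\n")
  print(x$table, ...)
  invisible(x)
}
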