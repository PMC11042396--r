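#' Fit the generalized propensity score model for log-TTS
#'
#' Maximum-likelihood normal linear model of `log(tts_days)` on indicator
#' codings of the supplied covariates (reference levels dropped).  The
#' residual SD and the marginal moments of log-TTS are maximum-likelihood
#' (n-denominator) estimates; the marginal moments feed the numerator of
#' the stabilized weight.
#'
#' @param cohort Screened cohort data frame (single subtype stratum in the
#'   published design; any cohort works).
#' @param covariates Covariate columns; see [gps_covariates()].
#' @return An object of class `gps_model`: coefficients (intercept first),
#'   `sigma`, `marginal_mean`, `marginal_sd`, the covariate list and `n`.
#' @export
fit_gps <- function(cohort, covariates) {
  if (any(cohort$tts_days <= 0)) {
    stop("log-TTS undefined: tts_days must be positive", call. = FALSE)
  }
  s <- log(cohort$tts_days)
  if (length(unique(cohort$tts_days)) < 2L) {
    stop("need >= 2 distinct TTS values", call. = FALSE)
  }
  Z <- .covariate_design(cohort, covariates)
  X <- cbind("(Intercept)" = 1, Z)
  fit <- lm.fit(X, s)
  res <- fit$residuals
  structure(list(
    coefs = setNames(fit$coefficients, colnames(X)),
    sigma = sqrt(mean(res^2)),
    marginal_mean = mean(s),
    marginal_sd = sqrt(mean((s - mean(s))^2)),
    covariates = covariates,
    balanced = FALSE,
    n = nrow(cohort)
  ), class = "gps_model")
}

.gps_conditional_mean <- function(model, cohort) {
  Z <- .covariate_design(cohort, model$covariates, check_rank = FALSE)
  X <- cbind(1, Z)
  if (!identical(ncol(X), length(model$coefs))) {
    stop("cohort design does not match the fitted GPS model", call. = FALSE)
  }
  drop(X %*% model$coefs)
}

#' Stabilized generalized-propensity-score weights
#'
#' Raw stabilized weight
#' `w_i = dnorm(logT_i; marginal mean, marginal sd) /
#'        dnorm(logT_i; fitted conditional mean, sigma)`.
#' Numerically vanishing conditional densities are floored at `eps` with a
#' warning so weights stay strictly positive.
#'
#' @param model A [fit_gps()] model (optionally refined by
#'   [balance_refine()]).
#' @param cohort The cohort the model was fitted on.
#' @param eps Density floor.
#' @return Object of class `tts_weights`: data frame `(id, raw)` with the
#'   `balanced` attribute of the model; [normalize_winsorize()] adds the
#'   final weights.
#' @export
stabilized_weights <- function(model, cohort, eps = 1e-300) {
  stopifnot(inherits(model, "gps_model"))
  s <- log(cohort$tts_days)
  mu <- .gps_conditional_mean(model, cohort)
  num <- dnorm(s, model$marginal_mean, model$marginal_sd)
  den <- dnorm(s, mu, model$sigma)
  if (any(den < eps)) {
    warning(sum(den < eps), " conditional densities floored at eps")
    den <- pmax(den, eps)
  }
  structure(data.frame(id = cohort$id, raw = num / den,
                       stringsAsFactors = FALSE),
            balanced = isTRUE(model$balanced),
            class = c("tts_weights", "data.frame"))
}

#' Covariate-balancing refinement of the GPS model
#'
#' Adjusts the conditional-mean coefficients of a fitted GPS model so that
#' the stabilized weights exactly decorrelate standardized log-TTS from
#' every standardized covariate indicator (and from the constant): the
#' just-identified continuous-treatment balancing moments
#' `sum_i w_i(beta) * s_i * [1, z_i] = 0` are solved by a damped Newton
#' root-finder with the analytic Jacobian, holding `sigma` and the marginal
#' moments at their ML values.  On non-convergence the ML model is returned
#' unchanged with a warning (never fatal).
#'
#' @param model A [fit_gps()] model.
#' @param cohort The cohort it was fitted on.
#' @param max_iter,tol Newton iteration cap and max-absolute-moment
#'   tolerance.
#' @return A `gps_model` with updated coefficients and `balanced = TRUE`
#'   (or the input model with `balanced = FALSE` if refinement failed).
#' @export
balance_refine <- function(model, cohort, max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(model, "gps_model"))
  s <- log(cohort$tts_days)
  Z <- .covariate_design(cohort, model$covariates)
  X <- cbind(1, Z)
  n <- nrow(X)
  s_std <- (s - model$marginal_mean) / model$marginal_sd
  Zs <- scale(Z)          # standardized indicators
  M <- cbind(1, Zs)       # moment instruments (constant + indicators)
  sig2 <- model$sigma^2
  lognum <- dnorm(s, model$marginal_mean, model$marginal_sd, log = TRUE)

  moment_fun <- function(beta) {
    mu <- drop(X %*% beta)
    w <- exp(lognum - dnorm(s, mu, model$sigma, log = TRUE))
    m <- crossprod(M, w * s_std) / n
    list(w = w, m = drop(m), mu = mu)
  }

  beta <- model$coefs
  st <- moment_fun(beta)
  converged <- max(abs(st$m)) < tol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    # d w_i / d beta_k = -w_i * (s_i - mu_i) * x_ik / sigma^2
    r <- s - st$mu
    J <- crossprod(M, (-st$w * r / sig2) * s_std * X) / n
    delta <- tryCatch(solve(J, -st$m), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- beta + step * delta
      st_new <- moment_fun(cand)
      if (all(is.finite(st_new$m)) &&
          (max(abs(st_new$m)) < max(abs(st$m)) || step < 1e-6)) break
      step <- step / 2
    }
    beta <- beta + step * delta
    st <- st_new
    converged <- max(abs(st$m)) < tol
  }
  if (!converged) {
    warning("balance refinement did not converge; returning ML fit")
    return(model)
  }
  model$coefs <- setNames(beta, names(model$coefs))
  model$balanced <- TRUE
  model
}

#' Normalize and winsorize weights
#'
#' Caps raw weights above the `cap_percentile` empirical quantile at that
#' quantile (upper tail only by default; `two_sided = TRUE` also caps the
#' lower `100 - cap_percentile` tail), then divides by the post-capping
#' mean so the final weights average exactly 1.
#'
#' @param weights A `tts_weights` object from [stabilized_weights()], or a
#'   positive numeric vector.
#' @param cap_percentile Winsorization percentile, in (50, 100]; default
#'   95.
#' @param two_sided Cap both tails?
#' @return A `tts_weights` data frame `(id, raw, capped, final)` with
#'   attributes `winsor_cap` (the capping value) and `cap_percentile`.
#' @export
normalize_winsorize <- function(weights, cap_percentile = 95,
                                two_sided = FALSE) {
  if (cap_percentile <= 50 || cap_percentile > 100) {
    stop("cap_percentile must lie in (50, 100]", call. = FALSE)
  }
  if (inherits(weights, "tts_weights")) {
    ws <- weights
    raw <- ws$raw
  } else {
    raw <- as.numeric(weights)
    ws <- structure(data.frame(id = as.character(seq_along(raw)), raw = raw,
                               stringsAsFactors = FALSE),
                    class = c("tts_weights", "data.frame"))
  }
  if (any(!is.finite(raw)) || any(raw <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  cap <- unname(quantile(raw, cap_percentile / 100, type = 7))
  capped <- pmin(raw, cap)
  if (two_sided) {
    lo <- unname(quantile(raw, 1 - cap_percentile / 100, type = 7))
    capped <- pmax(capped, lo)
  }
  ws$capped <- capped
  ws$final <- capped / mean(capped)
  attr(ws, "winsor_cap") <- cap
  attr(ws, "cap_percentile") <- cap_percentile
  ws
}

#' Exposure-covariate balance before and after weighting
#'
#' For each covariate indicator, the unweighted and the weighted Pearson
#' correlation with log-TTS -- the numbers a Love plot displays.
#' Zero-variance indicators are reported as `NA` and listed in the
#' `degenerate` attribute.
#'
#' @param cohort Cohort data frame.
#' @param weights Final weights (a `tts_weights` object or numeric vector
#'   aligned to the cohort).
#' @param covariates Covariates to check; see [gps_covariates()].
#' @return Data frame `(indicator, pre_cor, post_cor)`.
#' @export
balance_report <- function(cohort, weights, covariates) {
  w <- if (inherits(weights, "tts_weights")) {
    if (is.null(weights$final)) weights$raw else weights$final
  } else as.numeric(weights)
  stopifnot(length(w) == nrow(cohort))
  s <- log(cohort$tts_days)
  Z <- .covariate_design(cohort, covariates, check_rank = FALSE)
  degenerate <- character(0)
  pre <- post <- numeric(ncol(Z))
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    if (sd(z) == 0) {
      pre[j] <- post[j] <- NA_real_
      degenerate <- c(degenerate, colnames(Z)[j])
      next
    }
    pre[j] <- cor(z, s)
    post[j] <- .weighted_cor(z, s, w)
  }
  structure(data.frame(indicator = colnames(Z), pre_cor = pre,
                       post_cor = post, stringsAsFactors = FALSE),
            degenerate = degenerate,
            class = c("balance_report", "data.frame"))
}

#' Full weighting pipeline for one stratum
#'
#' Convenience wrapper running [fit_gps()], [balance_refine()],
#' [stabilized_weights()], [normalize_winsorize()] and [balance_report()]
#' in sequence.
#'
#' @inheritParams fit_gps
#' @param cap_percentile Winsorization percentile (default 95).
#' @param refine Apply the covariate-balancing refinement?
#' @param two_sided Two-sided winsorization?
#' @return List with `model`, `weights` (final `tts_weights`) and
#'   `balance`.
#' @export
weight_pipeline <- function(cohort, covariates, cap_percentile = 95,
                            refine = TRUE, two_sided = FALSE) {
  model <- fit_gps(cohort, covariates)
  if (refine) model <- balance_refine(model, cohort)
  ws <- stabilized_weights(model, cohort)
  ws <- normalize_winsorize(ws, cap_percentile, two_sided)
  list(model = model,
       weights = ws,
       balance = balance_report(cohort, ws, covariates))
}
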