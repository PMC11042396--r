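#' @keywords internal
#' @aliases ttsrisk-package
#' @useDynLib ttsrisk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm qnorm qchisq pchisq quantile rnorm runif rexp
#'   rbinom sd median setNames cor coef lm.fit as.formula model.matrix
#' @importFrom utils write.csv read.csv head
"_PACKAGE"

# Declared category orders for every categorical field.  The order is part of
# the interchange schema: it fixes factor levels in the cohort data frame,
# reference levels for indicator coding, and tie-breaking in modal profiles.
.tts_levels <- list(
  subtype      = c("hrpos_her2neg", "her2pos", "tnbc"),
  age_group    = c("lt70", "70_74", "75_79", "80_84", "85plus"),
  race_eth     = c("white", "black", "other"),
  cci          = c("0", "1", "2plus"),
  dx_year      = as.character(2010:2017),
  stage        = c("local", "regional_nodes"),
  histology    = c("ductal", "lobular", "other"),
  grade        = c("1", "2", "3_4"),
  surgery_type = c("bcs", "mastectomy", "mastectomy_recon"),
  chemo        = c("no", "yes"),
  radiation    = c("no", "yes"),
  hr_status    = c("pos", "neg")
)

# Raw eligibility flags carried by unscreened cohorts, in exclusion-cascade
# order for the flag-based rules (TTS window rules are interleaved; see
# apply_exclusions()).
.tts_flags <- c(
  "nonlocoregional", "prior_cancer", "nondefinitive_surgery",
  "missing_info", "followup_lt_tts", "death_lt_1yr"
)

.flag_cols <- function() paste0("flag_", .tts_flags)

.cohort_cols <- function() {
  c("id", "subtype", "tts_days", "surv_years", "event_type",
    names(.tts_levels)[-1L], .flag_cols())
}

#' Cohort schema levels
#'
#' Declared category orders for the categorical fields of the patient-level
#' cohort data frame (the interchange schema used by [read_cohort_csv()] and
#' produced by [generate_cohort()]).
#'
#' @return Named list of character vectors, one per categorical field.
#' @export
cohort_levels <- function() .tts_levels

#' Covariate sets used by the analysis
#'
#' `gps_covariates()` returns the socio-demographic and clinical factors used
#' as predictors of log-TTS in the generalized propensity score model;
#' `adjust_covariates()` returns the covariates entered directly into the
#' Fine-Gray model (adjuvant radiation, chemo/targeted therapy, comorbidity
#' score, plus hormone-receptor status within the HER2+ stratum).
#'
#' @param subtype One of `"hrpos_her2neg"`, `"her2pos"`, `"tnbc"`.
#' @return Character vector of covariate (column) names.
#' @export
gps_covariates <- function(subtype) {
  subtype <- match.arg(subtype, .tts_levels$subtype)
  base <- c("age_group", "race_eth", "cci", "dx_year", "stage", "histology",
            "grade", "surgery_type", "chemo", "radiation")
  if (subtype == "her2pos") c(base, "hr_status") else base
}

#' @rdname gps_covariates
#' @export
adjust_covariates <- function(subtype) {
  subtype <- match.arg(subtype, .tts_levels$subtype)
  base <- c("radiation", "chemo", "cci")
  if (subtype == "her2pos") c(base, "hr_status") else base
}

# Coerce categorical columns to factors with declared levels; error on
# out-of-enum values, naming the column and offending label.
.coerce_cohort <- function(df) {
  for (nm in names(.tts_levels)) {
    x <- as.character(df[[nm]])
    bad <- !is.na(x) & !(x %in% .tts_levels[[nm]])
    if (any(bad)) {
      stop(sprintf("column '%s': unknown level(s) %s (first at row %d)",
                   nm, paste(sQuote(unique(x[bad])), collapse = ", "),
                   which(bad)[1L]), call. = FALSE)
    }
    df[[nm]] <- factor(x, levels = .tts_levels[[nm]])
  }
  df
}

.validate_cohort <- function(df, require_flags = TRUE) {
  need <- .cohort_cols()
  if (!require_flags) need <- setdiff(need, .flag_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$tts_days)) || any(df$tts_days < 0)) {
    stop("tts_days must be a non-negative integer (first bad row: ",
         which(is.na(df$tts_days) | df$tts_days < 0)[1L], ")", call. = FALSE)
  }
  if (any(is.na(df$surv_years)) || any(df$surv_years < 0)) {
    stop("surv_years must be non-negative (first bad row: ",
         which(is.na(df$surv_years) | df$surv_years < 0)[1L], ")",
         call. = FALSE)
  }
  if (!all(df$event_type %in% c(0L, 1L, 2L))) {
    stop("event_type must be 0 (censored), 1 (breast-cancer death) or 2 ",
         "(other-cause death); first bad row: ",
         which(!(df$event_type %in% 0:2))[1L], call. = FALSE)
  }
  # subtype / hormone-receptor consistency
  bad <- (df$subtype == "tnbc" & df$hr_status != "neg") |
    (df$subtype == "hrpos_her2neg" & df$hr_status != "pos")
  if (any(bad, na.rm = TRUE)) {
    stop("subtype and hr_status are inconsistent at row ",
         which(bad)[1L], call. = FALSE)
  }
  invisible(df)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Sum per-level additive effects for each row of `data`.  `coefs` is a named
# list keyed by covariate; each element is a named numeric vector keyed by
# level (absent levels contribute 0, i.e. are reference levels).
.lookup_effects <- function(coefs, data) {
  eta <- numeric(nrow(data))
  for (cov in names(coefs)) {
    v <- coefs[[cov]]
    if (!length(v)) next
    hit <- v[as.character(data[[cov]])]
    hit[is.na(hit)] <- 0
    eta <- eta + unname(hit)
  }
  eta
}

# Indicator design matrix (reference levels dropped, no intercept column).
# Errors on rank deficiency, naming the collinear columns.
.covariate_design <- function(cohort, covariates, check_rank = TRUE) {
  stopifnot(length(covariates) >= 1L)
  dat <- cohort[covariates]
  for (nm in covariates) dat[[nm]] <- droplevels(dat[[nm]])
  mm <- model.matrix(as.formula(paste("~", paste(covariates, collapse = "+"))),
                     data = dat)
  Z <- mm[, -1L, drop = FALSE]
  if (check_rank && ncol(Z)) {
    qz <- qr(cbind(1, Z))
    if (qz$rank < ncol(Z) + 1L) {
      keep <- qz$pivot[seq_len(qz$rank)]
      drop_cols <- setdiff(seq_len(ncol(Z) + 1L), keep) - 1L
      stop("rank-deficient covariate design; collinear column(s): ",
           paste(colnames(Z)[drop_cols], collapse = ", "), call. = FALSE)
    }
  }
  Z
}

# Weighted Pearson correlation (weights need not sum to 1).
.weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}
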