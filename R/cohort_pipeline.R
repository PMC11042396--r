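#' Apply the study eligibility cascade
#'
#' Screens a raw cohort with the fixed, ordered exclusion rules:
#' (1) nonlocoregional disease, (2) prior cancer diagnosis,
#' (3) non-definitive initial surgery, (4) surgery within 7 days of biopsy
#' (TTS < 8), (5) surgery 120 days or later after biopsy (TTS >= 120),
#' (6) time of death under one year, (7) reported follow-up shorter than
#' TTS, (8) missing information.  Each record is attributed to the first
#' rule it matches; retained records have `8 <= tts_days <= 119` and no
#' raw flags set.  Running the cascade on an already-screened cohort is a
#' no-op (idempotence).
#'
#' @param raw Cohort data frame carrying `tts_days` and the `flag_*`
#'   columns.
#' @return A list with `cohort` (retained records) and `log`, an
#'   `exclusion_log` data frame of `(rule, n_excluded)` in cascade order
#'   with attributes `n_input` and `n_retained`
#'   (`n_input - sum(n_excluded) = n_retained` always).
#' @export
apply_exclusions <- function(raw) {
  if (nrow(raw)) .validate_cohort(raw)
  rules <- list(
    nonlocoregional       = function(d) d$flag_nonlocoregional,
    prior_cancer          = function(d) d$flag_prior_cancer,
    nondefinitive_surgery = function(d) d$flag_nondefinitive_surgery,
    tts_lt_8              = function(d) d$tts_days < 8L,
    tts_ge_120            = function(d) d$tts_days >= 120L,
    death_lt_1yr          = function(d) d$flag_death_lt_1yr,
    followup_lt_tts       = function(d) d$flag_followup_lt_tts,
    missing_info          = function(d) d$flag_missing_info
  )
  n_input <- nrow(raw)
  reason <- rep(NA_integer_, n_input)
  if (n_input) {
    for (k in seq_along(rules)) {
      hit <- rules[[k]](raw) & is.na(reason)
      reason[hit] <- k
    }
  }
  counts <- vapply(seq_along(rules),
                   function(k) sum(reason == k, na.rm = TRUE), integer(1L))
  log <- structure(
    data.frame(rule = names(rules), n_excluded = counts,
               stringsAsFactors = FALSE),
    n_input = n_input, n_retained = n_input - sum(counts),
    class = c("exclusion_log", "data.frame"))
  cohort <- raw[is.na(reason), , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Eligibility cascade:", attr(x, "n_input"), "records in,",
      attr(x, "n_retained"), "retained\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Descriptive TTS summary by subtype and covariate level
#'
#' For every subtype stratum and covariate level, reports the count, column
#' percent within the covariate, and the median and quartiles of TTS in
#' days.  Quartiles use the default linear-interpolation convention
#' (`stats::quantile` type 7), fixed here for reproducibility.  An `all`
#' row per subtype gives the stratum totals.  Empty strata yield `n = 0`
#' rows with `NA` quantiles.
#'
#' @param cohort Screened cohort data frame.
#' @param covariates Covariate columns to tabulate (default: every
#'   categorical field except subtype).
#' @return Data frame with columns `subtype`, `covariate`, `level`, `n`,
#'   `percent`, `median`, `q1`, `q3`.
#' @export
summarize_tts <- function(cohort,
                          covariates = setdiff(names(.tts_levels),
                                               "subtype")) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  .validate_cohort(cohort, require_flags = FALSE)
  qs <- function(x) {
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  }
  out <- list()
  for (st in .tts_levels$subtype) {
    sub <- cohort[cohort$subtype == st, , drop = FALSE]
    q <- qs(sub$tts_days)
    out[[length(out) + 1L]] <- data.frame(
      subtype = st, covariate = "all", level = "all", n = nrow(sub),
      percent = if (nrow(sub)) 100 else NA_real_,
      median = q[2L], q1 = q[1L], q3 = q[3L], stringsAsFactors = FALSE)
    for (cov in covariates) {
      n_cov <- nrow(sub)
      for (lv in .tts_levels[[cov]]) {
        x <- sub$tts_days[as.character(sub[[cov]]) == lv]
        q <- qs(x)
        out[[length(out) + 1L]] <- data.frame(
          subtype = st, covariate = cov, level = lv, n = length(x),
          percent = if (n_cov) 100 * length(x) / n_cov else NA_real_,
          median = q[2L], q1 = q[1L], q3 = q[3L], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Most common covariate profile within a subtype stratum
#'
#' Returns, for each requested covariate, the most frequent level in the
#' stratum; ties are broken by the declared category order (first wins) and
#' recorded in the `ties` attribute.  Used to condition adjusted cumulative
#' incidence functions on the modal patient profile.
#'
#' @param cohort Screened cohort data frame.
#' @param subtype Subtype stratum to profile.
#' @param covariates Covariates to profile (default: the Fine-Gray
#'   adjustment covariates for that subtype).
#' @return Named character vector of modal levels, with attribute `ties`
#'   naming covariates whose mode was tied.
#' @export
modal_profile <- function(cohort, subtype,
                          covariates = adjust_covariates(subtype)) {
  subtype <- match.arg(subtype, .tts_levels$subtype)
  sub <- cohort[cohort$subtype == subtype, , drop = FALSE]
  if (!nrow(sub)) stop("empty stratum for subtype ", subtype, call. = FALSE)
  ties <- character(0)
  prof <- vapply(covariates, function(cov) {
    tab <- table(factor(sub[[cov]], levels = .tts_levels[[cov]]))
    top <- which(tab == max(tab))
    if (length(top) > 1L) ties <<- c(ties, cov)
    names(tab)[top[1L]]
  }, character(1L))
  structure(prof, ties = ties)
}
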