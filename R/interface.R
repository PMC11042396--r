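#' Run configuration
#'
#' Assembles and validates the configuration of an end-to-end pipeline
#' run.  Fully serializable (YAML/JSON): a run is reproducible from its
#' persisted configuration alone, and all randomness flows from the single
#' `seed` through named sub-streams (cohort generation uses `seed`,
#' the CIF bootstrap for stratum k uses `seed + 1000 * k`).
#'
#' @param seed Integer master seed.
#' @param n Raw cohort size to simulate (ignored when `cohort_csv` given).
#' @param cohort_csv Optional path to an existing raw cohort CSV; when
#'   supplied the simulation step is skipped.
#' @param truth A [simulation_truth()] object or a named list of overrides
#'   to its defaults.
#' @param subtypes Subtype strata to analyse.
#' @param spline List of spline settings (`degree`, `interior_knots`,
#'   `df`, `boundary_knots`) passed to [build_spline_basis()].
#' @param cap_percentile Weight winsorization percentile.
#' @param refine_weights Apply the covariate-balancing refinement?
#' @param bootstrap_reps CIF bootstrap replicates (0 disables intervals).
#' @param tts_values,horizons CIF evaluation points.
#' @param outdir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n = 46600L, cohort_csv = NULL,
                       truth = list(), subtypes = .tts_levels$subtype,
                       spline = list(), cap_percentile = 95,
                       refine_weights = TRUE, bootstrap_reps = 0L,
                       tts_values = c(30, 60, 90, 120), horizons = c(5, 8),
                       outdir = "ttsrisk_run") {
  if (!inherits(truth, "simulation_truth")) {
    truth <- do.call(simulation_truth, as.list(truth))
  }
  subtypes <- match.arg(subtypes, .tts_levels$subtype, several.ok = TRUE)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 cohort_csv = cohort_csv, truth = truth,
                 subtypes = subtypes, spline = spline,
                 cap_percentile = cap_percentile,
                 refine_weights = isTRUE(refine_weights),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 tts_values = tts_values, horizons = horizons,
                 outdir = outdir),
            class = "run_config")
}

#' Read and write cohort CSV files
#'
#' The interchange schema is one row per patient with the columns of
#' [cohort_levels()] plus `id`, `tts_days`, `surv_years`, `event_type` and
#' the six `flag_*` booleans; categorical values are lowercase tokens.
#' Writing then reading reproduces the cohort exactly (`surv_years` is
#' serialized at full double precision).  Unknown columns, missing
#' columns, out-of-enum labels and invariant violations are errors naming
#' the offending column and row.
#'
#' @param path File path.
#' @return `read_cohort_csv` returns a validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"))
  extra <- setdiff(names(df), .cohort_cols())
  if (length(extra)) {
    stop("unknown column(s) in cohort CSV: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(.cohort_cols(), names(df))
  if (length(miss)) {
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- .coerce_cohort(df)
  df$tts_days <- as.integer(df$tts_days)
  df$event_type <- as.integer(df$event_type)
  for (fl in .flag_cols()) df[[fl]] <- as.logical(df[[fl]])
  .validate_cohort(df)
  df[.cohort_cols()]
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  .validate_cohort(cohort)
  out <- cohort[.cohort_cols()]
  for (nm in names(.tts_levels)) out[[nm]] <- as.character(out[[nm]])
  out$surv_years <- sprintf("%.17g", out$surv_years)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize and restore a Fine-Gray fit
#'
#' Writes the coefficient vector, robust covariance, spline metadata,
#' Breslow baseline step coordinates, censoring KM and convergence
#' diagnostics to JSON; `read_fit_json` reconstructs a `finegray_fit`
#' sufficient for [shr_curve()], [weekly_table()] and point-estimate
#' [adjusted_cif()].
#'
#' @param fit A [fit_finegray()] object.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "finegray_fit"))
  obj <- list(
    beta = as.list(fit$beta), Sigma = fit$Sigma,
    basis = fit$basis[c("degree", "interior_knots", "boundary_knots",
                        "n_basis")],
    spline_cols = fit$spline_cols, adjust = fit$adjust,
    adjust_levels = fit$adjust_levels,
    adjust_colnames = fit$adjust_colnames,
    baseline = fit$baseline, censor_km = fit$censor_km,
    loglik = fit$loglik, iter = fit$iter, converged = fit$converged,
    n = fit$n, n_event1 = fit$n_event1, n_event2 = fit$n_event2,
    weighted = fit$weighted)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(list(
    degree = as.integer(obj$basis$degree),
    interior_knots = as.numeric(obj$basis$interior_knots),
    boundary_knots = as.numeric(obj$basis$boundary_knots),
    n_basis = as.integer(obj$basis$n_basis)), class = "spline_basis")
  beta <- unlist(obj$beta)
  Sigma <- as.matrix(obj$Sigma)
  dimnames(Sigma) <- list(names(beta), names(beta))
  structure(list(
    beta = beta, Sigma = Sigma, info = NULL,
    se = sqrt(pmax(diag(Sigma), 0)),
    loglik = obj$loglik, iter = obj$iter, converged = obj$converged,
    basis = basis, spline_cols = as.integer(obj$spline_cols),
    adjust = as.character(obj$adjust),
    adjust_levels = lapply(obj$adjust_levels, as.character),
    adjust_colnames = as.character(obj$adjust_colnames),
    baseline = as.data.frame(obj$baseline),
    censor_km = as.data.frame(obj$censor_km),
    n = obj$n, n_event1 = obj$n_event1, n_event2 = obj$n_event2,
    weighted = obj$weighted), class = "finegray_fit")
}

.write_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a raw cohort, applies the eligibility cascade,
#' and for each requested subtype stratum: fits the balancing propensity
#' weights, the weighted spline Fine-Gray model, the hazard-ratio curve
#' with simultaneous bands, the weekly risk table, and the adjusted
#' cumulative incidence at the modal covariate profile.  All artifacts are
#' written under `config$outdir`; an identical configuration yields
#' byte-identical CSV/JSON outputs.
#'
#' @param config A [run_config()] object (or list of its arguments).
#' @return Invisibly, a list of in-memory results per subtype plus the
#'   exclusion log and the run summary.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  .write_log(logcon, "ttsrisk ", as.character(utils::packageVersion("ttsrisk")),
             " | R ", getRversion(), " | seed ", config$seed)

  stage <- "simulate"
  res <- tryCatch({
    raw <- if (is.null(config$cohort_csv)) {
      .write_log(logcon, "simulating raw cohort of n = ", config$n)
      generate_cohort(config$truth, config$n, seed = config$seed)
    } else {
      .write_log(logcon, "reading raw cohort from ", config$cohort_csv)
      read_cohort_csv(config$cohort_csv)
    }
    write_cohort_csv(raw, file.path(outdir, "cohort_raw.csv"))
    yaml::write_yaml(.truth_to_list(config$truth),
                     file.path(outdir, "truth.yaml"))

    stage <- "exclude"
    scr <- apply_exclusions(raw)
    write_cohort_csv(scr$cohort, file.path(outdir, "cohort_included.csv"))
    write.csv(scr$log, file.path(outdir, "exclusion_log.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(n_input = attr(scr$log, "n_input"),
           n_retained = attr(scr$log, "n_retained"),
           rules = scr$log),
      file.path(outdir, "exclusion_log.json"), auto_unbox = TRUE,
      digits = NA)
    .write_log(logcon, "exclusions: ", attr(scr$log, "n_input"), " -> ",
               attr(scr$log, "n_retained"), " retained")

    stage <- "summarize"
    write.csv(summarize_tts(scr$cohort),
              file.path(outdir, "tts_summary.csv"), row.names = FALSE)

    per_subtype <- list()
    for (k in seq_along(config$subtypes)) {
      st <- config$subtypes[k]
      stage <- paste0("weigh[", st, "]")
      stratum <- scr$cohort[scr$cohort$subtype == st, , drop = FALSE]
      .write_log(logcon, st, ": n = ", nrow(stratum), ", events = ",
                 sum(stratum$event_type == 1), "/",
                 sum(stratum$event_type == 2))
      wp <- weight_pipeline(stratum, gps_covariates(st),
                            cap_percentile = config$cap_percentile,
                            refine = config$refine_weights)
      write.csv(data.frame(id = wp$weights$id, raw = wp$weights$raw,
                           final = wp$weights$final),
                file.path(outdir, paste0("weights_", st, ".csv")),
                row.names = FALSE)
      write.csv(wp$balance,
                file.path(outdir, paste0("balance_", st, ".csv")),
                row.names = FALSE)

      stage <- paste0("fit[", st, "]")
      basis <- do.call(build_spline_basis,
                       c(list(tts_values = stratum$tts_days), config$spline))
      fit <- fit_finegray(stratum, basis = basis,
                          adjust = adjust_covariates(st), ipw = wp$weights)
      write_fit_json(fit, file.path(outdir, paste0("fit_", st, ".json")))
      .write_log(logcon, st, ": converged in ", fit$iter,
                 " iterations, loglik ", format(fit$loglik))

      stage <- paste0("curves[", st, "]")
      curve <- shr_curve(fit)
      write.csv(curve, file.path(outdir, paste0("curve_", st, ".csv")),
                row.names = FALSE)
      wk <- weekly_table(curve)
      write.csv(wk, file.path(outdir, paste0("weekly_", st, ".csv")),
                row.names = FALSE)

      stage <- paste0("cif[", st, "]")
      prof <- modal_profile(scr$cohort, st)
      refit <- function(boot) {
        wpb <- weight_pipeline(boot, gps_covariates(st),
                               cap_percentile = config$cap_percentile,
                               refine = config$refine_weights)
        fit_finegray(boot, basis = basis, adjust = adjust_covariates(st),
                     ipw = wpb$weights)
      }
      cif <- adjusted_cif(fit, as.list(prof),
                          tts_values = config$tts_values,
                          horizons = config$horizons,
                          bootstrap_reps = config$bootstrap_reps,
                          seed = config$seed + 1000L * k,
                          cohort = stratum, refit_fun = refit)
      write.csv(cif$table, file.path(outdir, paste0("cif_", st, ".csv")),
                row.names = FALSE)
      per_subtype[[st]] <- list(weights = wp, fit = fit, curve = curve,
                                weekly = wk, profile = prof, cif = cif)
    }

    stage <- "summary"
    summ <- list(
      seed = config$seed,
      n_raw = nrow(raw),
      n_retained = attr(scr$log, "n_retained"),
      subtypes = lapply(per_subtype, function(r) list(
        n = r$fit$n, n_event1 = r$fit$n_event1, n_event2 = r$fit$n_event2,
        converged = r$fit$converged,
        winsor_cap = attr(r$weights$weights, "winsor_cap"),
        profile = as.list(r$profile),
        n_significant_days = sum(r$curve$significant))))
    jsonlite::write_json(summ, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(raw = raw, cohort = scr$cohort, exclusion_log = scr$log,
         subtypes = per_subtype, summary = summ)
  }, error = function(e) {
    .write_log(logcon, "ERROR at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  .write_log(logcon, "run complete")
  invisible(res)
}

.truth_to_list <- function(truth) {
  out <- unclass(truth)
  out$tts_confounding_coefs <- lapply(out$tts_confounding_coefs, as.list)
  out$covariate_coefs_cause1 <- lapply(out$covariate_coefs_cause1, as.list)
  out$cause2_rate$coefs <- lapply(out$cause2_rate$coefs, as.list)
  out$covariate_marginals <- lapply(out$covariate_marginals, as.list)
  out$subtype_probs <- as.list(out$subtype_probs)
  out$baseline_cause1_prob <- as.list(out$baseline_cause1_prob)
  out
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key,
                                     call. = FALSE)
    opts[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) {
    yaml::read_yaml(opts$config)
  } else {
    list()
  }
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$n)) cfg$n <- as.integer(opts$n)
  if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
  do.call(run_config, cfg)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, used by the
#' `inst/scripts/ttsrisk` wrapper.  Subcommands: `simulate` (write a raw
#' cohort CSV), `exclude` (apply the eligibility cascade to `--in`),
#' `weigh`, `fit`, `curves`, `cif` (per-subtype steps operating on CSV /
#' JSON artifacts in `--outdir`), and `run-all` ([run_pipeline()]).  Every
#' subcommand accepts `--config <yaml>` and `--seed <int>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched step.
#' @export
tts_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: ttsrisk <simulate|exclude|weigh|fit|curves|cif|run-all> ",
         "[--config cfg.yaml] [--seed n] ...", call. = FALSE)
  }
  cmd <- args[1L]
  opts <- .cli_opts(args[-1L])
  cfg <- .cli_config(opts)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st_list <- if (!is.null(opts$subtype)) opts$subtype else cfg$subtypes

  read_included <- function() {
    read_cohort_csv(file.path(outdir, "cohort_included.csv"))
  }
  res <- switch(cmd,
    "simulate" = {
      raw <- generate_cohort(cfg$truth, cfg$n, seed = cfg$seed)
      path <- if (!is.null(opts$out)) opts$out else
        file.path(outdir, "cohort_raw.csv")
      write_cohort_csv(raw, path)
      yaml::write_yaml(.truth_to_list(cfg$truth),
                       file.path(outdir, "truth.yaml"))
      message("wrote ", path)
      raw
    },
    "exclude" = {
      src <- if (!is.null(opts[["in"]])) opts[["in"]] else
        file.path(outdir, "cohort_raw.csv")
      scr <- apply_exclusions(read_cohort_csv(src))
      write_cohort_csv(scr$cohort, file.path(outdir, "cohort_included.csv"))
      write.csv(scr$log, file.path(outdir, "exclusion_log.csv"),
                row.names = FALSE)
      message("retained ", attr(scr$log, "n_retained"), " of ",
              attr(scr$log, "n_input"))
      scr
    },
    "weigh" = {
      cohort <- read_included()
      for (st in st_list) {
        wp <- weight_pipeline(cohort[cohort$subtype == st, ],
                              gps_covariates(st),
                              cap_percentile = cfg$cap_percentile,
                              refine = cfg$refine_weights)
        write.csv(data.frame(id = wp$weights$id, raw = wp$weights$raw,
                             final = wp$weights$final),
                  file.path(outdir, paste0("weights_", st, ".csv")),
                  row.names = FALSE)
        write.csv(wp$balance,
                  file.path(outdir, paste0("balance_", st, ".csv")),
                  row.names = FALSE)
      }
      invisible(NULL)
    },
    "fit" = {
      cohort <- read_included()
      for (st in st_list) {
        stratum <- cohort[cohort$subtype == st, ]
        w <- read.csv(file.path(outdir, paste0("weights_", st, ".csv")),
                      colClasses = c(id = "character"))
        w <- w[match(stratum$id, w$id), ]
        basis <- do.call(build_spline_basis,
                         c(list(tts_values = stratum$tts_days), cfg$spline))
        fit <- fit_finegray(stratum, basis = basis,
                            adjust = adjust_covariates(st), ipw = w$final)
        write_fit_json(fit, file.path(outdir, paste0("fit_", st, ".json")))
      }
      invisible(NULL)
    },
    "curves" = {
      for (st in st_list) {
        fit <- read_fit_json(file.path(outdir, paste0("fit_", st, ".json")))
        curve <- shr_curve(fit)
        write.csv(curve, file.path(outdir, paste0("curve_", st, ".csv")),
                  row.names = FALSE)
        write.csv(weekly_table(curve),
                  file.path(outdir, paste0("weekly_", st, ".csv")),
                  row.names = FALSE)
      }
      invisible(NULL)
    },
    "cif" = {
      cohort <- read_included()
      for (st in st_list) {
        fit <- read_fit_json(file.path(outdir, paste0("fit_", st, ".json")))
        prof <- modal_profile(cohort, st)
        cif <- adjusted_cif(fit, as.list(prof),
                            tts_values = cfg$tts_values,
                            horizons = cfg$horizons)
        write.csv(cif$table, file.path(outdir, paste0("cif_", st, ".csv")),
                  row.names = FALSE)
      }
      invisible(NULL)
    },
    "run-all" = run_pipeline(cfg),
    stop("unknown subcommand '", cmd, "'", call. = FALSE))
  invisible(res)
}
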