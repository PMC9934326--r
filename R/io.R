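#' Read and validate the three analysis tables
#'
#' Reads `baseline.csv`, `longitudinal.csv` and `survival.csv`, coerces the
#' categorical covariates to their canonical factor levels, and
#' cross-validates: every id must appear in all tables it is referenced
#' from, longitudinal `(id, time)` pairs must be unique, times non-negative
#' and (when given) within the administrative censoring limit.
#'
#' @param baseline_path,longitudinal_path,survival_path CSV paths.
#' @param admin_censor_time optional upper bound for longitudinal times.
#' @return list with validated `baseline`, `longitudinal`, `survival` data
#'   frames.
#' @export
read_tables <- function(baseline_path, longitudinal_path, survival_path,
                        admin_censor_time = NULL) {
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s is missing required column(s): %s", file,
                   paste(miss, collapse = ", ")))
  }
  baseline <- utils::read.csv(baseline_path, stringsAsFactors = FALSE)
  long <- utils::read.csv(longitudinal_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  need(baseline, "id", "baseline table")
  need(long, c("id", "time_months", "sbp_mmhg", "dbp_mmhg"),
       "longitudinal table")
  need(surv, c("id", "time_months", "event"), "survival table")
  for (cov in intersect(names(covariate_levels()), names(baseline))) {
    lv <- covariate_levels()[[cov]]
    bad <- !(baseline[[cov]] %in% lv)
    if (any(bad))
      stop(sprintf("baseline row %d: unknown category '%s' for '%s'",
                   which(bad)[1], baseline[[cov]][which(bad)[1]], cov))
    baseline[[cov]] <- factor(baseline[[cov]], levels = lv)
  }
  if (anyDuplicated(baseline$id))
    stop("duplicate subject ids in baseline table")
  orphan <- setdiff(long$id, surv$id)
  if (length(orphan))
    stop(sprintf("longitudinal ids absent from survival table: %s",
                 paste(utils::head(orphan, 5), collapse = ", ")))
  orphan <- setdiff(c(long$id, surv$id), baseline$id)
  if (length(orphan))
    stop(sprintf("ids absent from baseline table: %s",
                 paste(utils::head(orphan, 5), collapse = ", ")))
  if (any(long$time_months < 0))
    stop(sprintf("longitudinal row %d has negative time",
                 which(long$time_months < 0)[1]))
  if (!is.null(admin_censor_time) &&
      any(long$time_months > admin_censor_time))
    stop(sprintf("longitudinal row %d exceeds the administrative limit",
                 which(long$time_months > admin_censor_time)[1]))
  dup <- duplicated(long[, c("id", "time_months")])
  if (any(dup))
    stop(sprintf("duplicate (id, time) longitudinal row %d", which(dup)[1]))
  if (any(surv$time_months < 0))
    stop("negative time in survival table")
  if (!all(surv$event %in% c(0, 1)))
    stop("survival event indicator must be 0 or 1")
  list(baseline = baseline, longitudinal = long, survival = surv)
}

#' Write the fit report files
#'
#' Writes `summary.csv` (one row per parameter: posterior mean, time-series
#' SE, posterior SD, 2.5%/97.5% quantiles, R-hat, ESS), a machine-readable
#' `report.json` including hazard-ratio transforms of the survival and
#' association coefficients plus convergence diagnostics, and a
#' `summary_display.csv` rounded to 4 decimals.
#'
#' @param fit a `bp_joint_fit` from [run_mcmc()].
#' @param dir output directory (created if needed).
#' @param descriptives optional [baseline_summary()] output to embed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(fit, dir, descriptives = NULL) {
  stopifnot(inherits(fit, "bp_joint_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- fit$summary[, c("parameter", "mean", "se", "sd", "q2.5", "q97.5",
                       "rhat", "ess")]
  p_sum <- file.path(dir, "summary.csv")
  utils::write.csv(s, p_sum, row.names = FALSE)
  disp <- s
  num <- vapply(disp, is.numeric, TRUE)
  disp[num] <- lapply(disp[num], function(x) round(x, 4))
  p_disp <- file.path(dir, "summary_display.csv")
  utils::write.csv(disp, p_disp, row.names = FALSE)
  all <- do.call(rbind, fit$draws)
  hr_rows <- grep("^(surv:|assoc:)", fit$summary$parameter, value = TRUE)
  hrs <- lapply(hr_rows, function(p) {
    x <- all[, p]
    if (stats::sd(x) == 0 && mean(x) == 0) return(NULL)
    c(list(parameter = p), hazard_ratio_summary(x))
  })
  hrs <- hrs[!vapply(hrs, is.null, TRUE)]
  report <- list(summary = s,
                 hazard_ratios = hrs,
                 diagnostics = list(
                   max_rhat = max(s$rhat, na.rm = TRUE),
                   min_ess = min(s$ess, na.rm = TRUE),
                   not_converged = fit$not_converged,
                   acceptance = colMeans(fit$accept)),
                 control = unclass(fit$control),
                 seed = fit$seed)
  if (!is.null(descriptives)) report$descriptives <- descriptives
  p_json <- file.path(dir, "report.json")
  jsonlite::write_json(report, p_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(p_sum, p_disp, p_json))
}

#' Read a YAML run configuration
#'
#' Converts a YAML file with optional `cohort`, `design`, `mcmc` and `seed`
#' sections into the corresponding [cohort_config()], [design_spec()] and
#' [mcmc_control()] objects; omitted fields keep package defaults.
#'
#' @param path YAML file path.
#' @return list with `cohort`, `design`, `mcmc`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- do.call(cohort_config, utils::modifyList(
    list(), y$cohort %||% list()))
  ds <- do.call(design_spec, y$design %||% list())
  mc <- do.call(mcmc_control, y$mcmc %||% list())
  list(cohort = cc, design = ds, mcmc = mc, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
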