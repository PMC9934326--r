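# Truncated-normal sampling by inverse CDF, so a fixed RNG stream maps
# deterministically to draws regardless of truncation bounds.
rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Sample baseline covariates for a synthetic cohort
#'
#' Categorical covariates are drawn independently from their configured
#' category frequencies; continuous covariates from truncated normal
#' distributions with the configured moments and plausibility bounds (age is
#' truncated at the 15-year inclusion minimum).
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per subject: `id`, factor covariates
#'   (`sex`, `residence`, `dm`, `ckd`, `stroke`, `hiv`, `regimen`, `drug`)
#'   and numeric labs/age. `n_subjects = 0` yields an empty, well-typed
#'   table.
#' @export
sample_baseline <- function(config) {
  stopifnot(inherits(config, "bp_cohort_config"))
  n <- config$n_subjects
  out <- data.frame(id = seq_len(n))
  for (cov in names(config$covariate_frequencies)) {
    p <- config$covariate_frequencies[[cov]]
    draw <- if (n > 0) sample(names(p), n, replace = TRUE, prob = p)
            else character(0)
    out[[cov]] <- factor(draw, levels = names(p))
  }
  for (cov in names(config$covariate_moments)) {
    mm <- config$covariate_moments[[cov]]
    out[[cov]] <- if (n > 0) rtnorm(n, mm$mean, mm$sd, mm$lower, mm$upper)
                  else numeric(0)
  }
  out
}

#' Sample subject-level random effects
#'
#' Zero-mean multivariate normal draws of the per-subject
#' `(a_sbp, b_sbp, a_dbp, b_dbp)` vector with the given covariance, via the
#' symmetric matrix square root (so any positive semidefinite covariance is
#' accepted, including the zero matrix).
#'
#' @param n number of subjects.
#' @param covariance 4x4 symmetric positive semidefinite matrix.
#' @param seed optional integer seed.
#' @return `n` x 4 matrix with columns `a_sbp`, `b_sbp`, `a_dbp`, `b_dbp`.
#' @export
sample_random_effects <- function(n, covariance, seed = NULL) {
  stopifnot(is.matrix(covariance), nrow(covariance) == ncol(covariance))
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("covariance decomposition failed: matrix is not positive semidefinite")
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(covariance)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * d), n, d)
  out <- z %*% rt
  colnames(out) <- if (d == 4) re_names() else colnames(covariance)
  out
}

#' Simulate observed marker trajectories over a visit schedule
#'
#' For every subject and visit, the observed SBP/DBP is the true trajectory
#' value ([marker_mean()]) plus independent Gaussian measurement noise with
#' the marker-specific residual SD.
#'
#' @param baseline baseline table from [sample_baseline()].
#' @param effects random-effect matrix, one row per subject.
#' @param truth a [joint_params()] (or [lmm_params()]) supplying the
#'   trajectory parameters.
#' @param schedule visit times in months (non-empty).
#' @return list with `observed` (data frame `id`, `time_months`, `sbp_mmhg`,
#'   `dbp_mmhg`) and `true` (same layout, noise-free, columns `sbp_true`,
#'   `dbp_true`).
#' @export
sample_trajectories <- function(baseline, effects, truth, schedule) {
  lmm <- if (inherits(truth, "bp_joint_params")) truth$lmm else truth
  stopifnot(inherits(lmm, "bp_lmm_params"))
  if (length(schedule) == 0) stop("visit schedule must be non-empty")
  n <- nrow(baseline)
  if (n > 0 && (is.null(effects) || nrow(effects) != n))
    stop("effects must have one row per subject")
  sched <- as.numeric(schedule)
  nv <- length(sched)
  id <- rep(baseline$id, each = nv)
  tt <- rep(sched, times = n)
  W1 <- covariate_matrix(baseline, lmm$spec$sbp)
  W2 <- covariate_matrix(baseline, lmm$spec$dbp)
  b1 <- align_coef(lmm$beta$sbp, c("(Intercept)", "time", colnames(W1)),
                   "SBP")
  b2 <- align_coef(lmm$beta$dbp, c("(Intercept)", "time", colnames(W2)),
                   "DBP")
  if (n > 0) {
    c1 <- b1[1] + drop(W1 %*% b1[-(1:2)]) + effects[, 1]
    c2 <- b2[1] + drop(W2 %*% b2[-(1:2)]) + effects[, 3]
    s1 <- b1[2] + effects[, 2]
    s2 <- b2[2] + effects[, 4]
  } else c1 <- c2 <- s1 <- s2 <- numeric(0)
  ii <- rep(seq_len(n), each = nv)
  true1 <- c1[ii] + s1[ii] * tt
  true2 <- c2[ii] + s2[ii] * tt
  obs1 <- true1 + stats::rnorm(length(tt), 0, lmm$sigma_eps[["sbp"]])
  obs2 <- true2 + stats::rnorm(length(tt), 0, lmm$sigma_eps[["dbp"]])
  list(observed = data.frame(id = id, time_months = tt, sbp_mmhg = obs1,
                             dbp_mmhg = obs2),
       true = data.frame(id = id, time_months = tt, sbp_true = true1,
                         dbp_true = true2))
}

#' Draw one subject's event time by inverting the cumulative hazard
#'
#' Solves `Lambda(T) = -log(u)` for `T` by bracketed root finding on the
#' subject's cumulative hazard. If even the cumulative hazard at the
#' administrative censoring time is below `-log(u)`, the subject is censored
#' there.
#'
#' @param truth a [joint_params()] with the hazard and trajectory parameters.
#' @param row single-row baseline data frame.
#' @param b length-4 random-effect vector.
#' @param u uniform(0,1) draw.
#' @param admin_censor_time administrative censoring time, months.
#' @return list with `time` (months) and `event` (1 = remission, 0 =
#'   censored).
#' @export
sample_event_time <- function(truth, row, b, u, admin_censor_time) {
  stopifnot(inherits(truth, "bp_joint_params"), u > 0, u < 1,
            admin_censor_time > 0)
  target <- -log(u)
  lp <- hazard_linpred(truth$hazard, truth$lmm, row, b)
  f <- function(T) cumhaz_lp(T, truth$hazard, lp$const, lp$slope) - target
  if (f(admin_censor_time) < 0)
    return(list(time = admin_censor_time, event = 0L))
  root <- tryCatch(
    stats::uniroot(f, c(0, admin_censor_time), tol = 1e-10, maxiter = 200),
    error = function(e)
      stop(sprintf("event-time root finding failed for subject %s: %s",
                   as.character(row$id[1]), conditionMessage(e))))
  list(time = root$root, event = 1L)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [sample_baseline()], [sample_random_effects()],
#' [sample_event_time()] and [sample_trajectories()] into the three analysis
#' tables. Longitudinal rows after a subject's exit (event or censoring) are
#' dropped, matching registry data where visits stop at exit. The full
#' pipeline is deterministic for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param truth a [joint_params()] used as simulation ground truth.
#' @param seed integer seed; falls back to `config$seed`.
#' @return object of class `bp_cohort`: list with `baseline`,
#'   `longitudinal` (including a `controlled` diagnostic flag for visits with
#'   observed SBP < 140 and DBP < 90), `survival`, `true_trajectories`,
#'   `effects`, `truth` and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            truth = default_truth(),
                            seed = config$seed) {
  stopifnot(inherits(config, "bp_cohort_config"),
            inherits(truth, "bp_joint_params"))
  if (is.null(seed)) stop("a seed is required for cohort generation")
  set.seed(seed)
  baseline <- sample_baseline(config)
  n <- nrow(baseline)
  effects <- sample_random_effects(n, truth$lmm$Sigma)
  u <- stats::runif(n)
  dropout <- if (config$dropout_rate > 0)
    stats::rexp(n, config$dropout_rate) else rep(Inf, n)
  times <- numeric(n); events <- integer(n)
  for (i in seq_len(n)) {
    ev <- sample_event_time(truth, baseline[i, , drop = FALSE], effects[i, ],
                            u[i], config$admin_censor_time)
    if (dropout[i] < ev$time) {
      times[i] <- dropout[i]; events[i] <- 0L
    } else {
      times[i] <- ev$time; events[i] <- ev$event
    }
  }
  traj <- sample_trajectories(baseline, effects, truth,
                              config$visit_schedule)
  keep <- traj$observed$time_months <= times[match(traj$observed$id,
                                                   baseline$id)]
  longitudinal <- traj$observed[keep, , drop = FALSE]
  rownames(longitudinal) <- NULL
  longitudinal$controlled <- longitudinal$sbp_mmhg < 140 &
    longitudinal$dbp_mmhg < 90
  surv <- data.frame(id = baseline$id, time_months = times, event = events)
  structure(list(baseline = baseline,
                 longitudinal = longitudinal,
                 survival = surv,
                 true_trajectories = traj$true[keep, , drop = FALSE],
                 effects = effects,
                 truth = truth,
                 config = config,
                 seed = seed),
            class = "bp_cohort")
}

#' Write a synthetic cohort to CSV plus a truth record
#'
#' Writes `baseline.csv`, `longitudinal.csv` (`id`, `time_months`,
#' `sbp_mmhg`, `dbp_mmhg`), `survival.csv` (`id`, `time_months`, `event`)
#' and `truth.json` holding the generating parameters and seed.
#'
#' @param cohort a `bp_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("baseline.csv", "longitudinal.csv",
                            "survival.csv", "truth.json"))
  utils::write.csv(cohort$baseline, paths[1], row.names = FALSE)
  long <- cohort$longitudinal[, c("id", "time_months", "sbp_mmhg",
                                  "dbp_mmhg")]
  utils::write.csv(long, paths[2], row.names = FALSE)
  utils::write.csv(cohort$survival, paths[3], row.names = FALSE)
  truth <- cohort$truth
  rec <- list(seed = cohort$seed,
              beta_sbp = as.list(truth$lmm$beta$sbp),
              beta_dbp = as.list(truth$lmm$beta$dbp),
              Sigma = truth$lmm$Sigma,
              sigma_eps = as.list(truth$lmm$sigma_eps),
              log_levels = truth$hazard$log_levels,
              knots = truth$hazard$knots,
              gamma = as.list(truth$hazard$gamma),
              rho = as.list(truth$hazard$rho))
  jsonlite::write_json(rec, paths[4], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
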