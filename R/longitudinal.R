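#' True marker values for one subject
#'
#' Evaluates the noise-free trajectory `m(t) = X(t)'beta + Z(t)'b + u'delta`
#' of both markers: the fixed linear predictor plus the subject's random
#' intercept and slope.
#'
#' @param params a [lmm_params()] object.
#' @param b length-4 random-effect vector `(a_sbp, b_sbp, a_dbp, b_dbp)`.
#' @param row single-row baseline data frame for the subject.
#' @param time numeric vector of times, months.
#' @return matrix with `length(time)` rows and columns `sbp`, `dbp` (mmHg).
#' @export
marker_mean <- function(params, b, row, time) {
  stopifnot(inherits(params, "bp_lmm_params"), length(b) == 4)
  d0 <- build_design(row, 0, params$spec)
  int1 <- sum(align_coef(params$beta$sbp, names(d0$sbp), "SBP")[-2] *
                d0$sbp[-2]) + b[1]
  int2 <- sum(align_coef(params$beta$dbp, names(d0$dbp), "DBP")[-2] *
                d0$dbp[-2]) + b[3]
  s1 <- params$beta$sbp[["time"]] + b[2]
  s2 <- params$beta$dbp[["time"]] + b[4]
  cbind(sbp = int1 + s1 * time, dbp = int2 + s2 * time)
}

#' True marker slopes for one subject
#'
#' Under the linear-in-time design the slope of each marker's true trajectory
#' is the fixed time coefficient plus the subject's random slope, constant in
#' `t`.
#'
#' @inheritParams marker_mean
#' @return matrix with columns `sbp`, `dbp` (mmHg/month), one row per time.
#' @export
marker_slope <- function(params, b, row, time) {
  stopifnot(inherits(params, "bp_lmm_params"), length(b) == 4)
  cbind(sbp = rep(params$beta$sbp[["time"]] + b[2], length(time)),
        dbp = rep(params$beta$dbp[["time"]] + b[4], length(time)))
}

#' Model-implied marginal covariance of the observed markers at time t
#'
#' Integrating the random effects out of the mixed model, the observed
#' `(SBP, DBP)` at time `t` have covariance
#' `z' Sigma_block z` per block with `z = (1, t)`, plus the residual variance
#' on the diagonal. The implied correlation is the "evolution of association"
#' between the two pressures over the visit schedule.
#'
#' @param params a [lmm_params()] object.
#' @param t time, months (scalar, >= 0).
#' @return list with `covariance` (2x2 matrix, mmHg^2) and `correlation`
#'   (scalar).
#' @export
#' @examples
#' marginal_covariance(default_truth()$lmm, 0)$correlation # about 0.26
marginal_covariance <- function(params, t) {
  stopifnot(inherits(params, "bp_lmm_params"), is.numeric(t), length(t) == 1,
            t >= 0)
  check_psd(params$Sigma)
  z <- c(1, t)
  S <- params$Sigma
  v1 <- drop(z %*% S[1:2, 1:2] %*% z) + params$sigma_eps[["sbp"]]^2
  v2 <- drop(z %*% S[3:4, 3:4] %*% z) + params$sigma_eps[["dbp"]]^2
  cv <- drop(z %*% S[1:2, 3:4] %*% z)
  V <- matrix(c(v1, cv, cv, v2), 2, dimnames = list(c("sbp", "dbp"),
                                                    c("sbp", "dbp")))
  corr <- if (v1 > 0 && v2 > 0) cv / sqrt(v1 * v2) else 0
  list(covariance = V, correlation = corr)
}

#' Log-likelihood of the longitudinal observations
#'
#' Sum of independent Gaussian log-densities of the observed pressures around
#' the subject-specific true trajectories, over subjects, visits and both
#' markers.
#'
#' @param params a [lmm_params()] object with strictly positive residual SDs.
#' @param effects matrix of per-subject random effects (rows in the order of
#'   `baseline$id`), 4 columns.
#' @param longitudinal data frame with columns `id`, `time_months`,
#'   `sbp_mmhg`, `dbp_mmhg`.
#' @param baseline baseline covariate data frame with column `id`.
#' @return scalar log-density.
#' @export
loglik_longitudinal <- function(params, effects, longitudinal, baseline) {
  stopifnot(inherits(params, "bp_lmm_params"))
  if (any(params$sigma_eps <= 0))
    stop("residual SDs must be strictly positive")
  if (nrow(longitudinal) == 0) return(0)
  idx <- match(longitudinal$id, baseline$id)
  if (anyNA(idx)) stop("longitudinal ids missing from baseline table")
  X1 <- cbind(1, longitudinal$time_months,
              covariate_matrix(baseline, params$spec$sbp)[idx, , drop = FALSE])
  X2 <- cbind(1, longitudinal$time_months,
              covariate_matrix(baseline, params$spec$dbp)[idx, , drop = FALSE])
  b1 <- align_coef(params$beta$sbp,
                   c("(Intercept)", "time",
                     colnames(covariate_matrix(baseline[0, , drop = FALSE],
                                               params$spec$sbp))), "SBP")
  b2 <- align_coef(params$beta$dbp,
                   c("(Intercept)", "time",
                     colnames(covariate_matrix(baseline[0, , drop = FALSE],
                                               params$spec$dbp))), "DBP")
  t <- longitudinal$time_months
  mu1 <- drop(X1 %*% b1) + effects[idx, 1] + effects[idx, 2] * t
  mu2 <- drop(X2 %*% b2) + effects[idx, 3] + effects[idx, 4] * t
  sum(stats::dnorm(longitudinal$sbp_mmhg, mu1, params$sigma_eps[["sbp"]],
                   log = TRUE)) +
    sum(stats::dnorm(longitudinal$dbp_mmhg, mu2, params$sigma_eps[["dbp"]],
                     log = TRUE))
}
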