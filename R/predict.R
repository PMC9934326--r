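# Reconstruct a joint_params object from one stored draw of a fit.
params_from_draw <- function(fit, draw) {
  spec <- fit$spec
  g <- function(prefix) {
    sel <- startsWith(names(draw), prefix)
    stats::setNames(draw[sel], substring(names(draw)[sel],
                                         nchar(prefix) + 1))
  }
  sds <- unname(g("re_sd:"))
  rc <- unname(g("re_corr:"))
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- rc[1]; R[1, 3] <- R[3, 1] <- rc[2]
  R[1, 4] <- R[4, 1] <- rc[3]; R[2, 3] <- R[3, 2] <- rc[4]
  R[2, 4] <- R[4, 2] <- rc[5]; R[3, 4] <- R[4, 3] <- rc[6]
  lmm <- lmm_params(beta_sbp = g("sbp:"), beta_dbp = g("dbp:"),
                    Sigma = sigma_from_sd_corr(sds, R),
                    sigma_eps = c(draw[["sigma:sbp"]], draw[["sigma:dbp"]]),
                    spec = spec)
  hz <- hazard_params(log_levels = unname(g("logh0:")), knots = fit$knots,
                      gamma = g("surv:"), rho = unname(g("assoc:")))
  joint_params(lmm, hz,
               shrinkage_hyper(draw[["tau"]], unname(g("psi:"))))
}

#' Dynamic prediction of conditional remission-free probability
#'
#' Monte-Carlo estimate of `S(u | T > t, history)` for a new subject with
#' longitudinal measurements up to `t`. For each posterior draw the subject's
#' random effects are sampled by a short Metropolis run against the history
#' likelihood (longitudinal records, random-effect prior, and survival to
#' `t`), then the conditional survival `exp(-(Lambda(u) - Lambda(t)))` is
#' evaluated; the posterior mean and central credible band are returned per
#' horizon.
#'
#' @param fit a `bp_joint_fit` from [run_mcmc()], or a [joint_params()]
#'   object for a fixed-parameter prediction.
#' @param row single-row baseline data frame for the subject.
#' @param history data frame of the subject's longitudinal records
#'   (`time_months`, `sbp_mmhg`, `dbp_mmhg`); at least one row.
#' @param t_obs time the subject is known remission-free to, months.
#' @param horizons prediction times `u > t_obs`, months.
#' @param ndraws number of posterior draws to use.
#' @param mh_steps Metropolis steps per draw for the random effects.
#' @param seed integer seed.
#' @return data frame with columns `horizon`, `mean`, `lower`, `upper`.
#' @export
dynamic_prediction <- function(fit, row, history, t_obs, horizons,
                               ndraws = 200, mh_steps = 10, seed = 1) {
  stopifnot(nrow(history) >= 1, t_obs >= 0)
  if (any(horizons < t_obs))
    stop("prediction horizons must not precede t_obs")
  set.seed(seed)
  if (inherits(fit, "bp_joint_params")) {
    par_list <- list(fit)
  } else {
    all <- do.call(rbind, fit$draws)
    take <- unique(round(seq(1, nrow(all), length.out = min(ndraws,
                                                            nrow(all)))))
    par_list <- lapply(take, function(j) params_from_draw(fit, all[j, ]))
  }
  nh <- length(horizons)
  S <- matrix(NA_real_, length(par_list), nh)
  b <- numeric(4)
  for (j in seq_along(par_list)) {
    p <- par_list[[j]]
    lp_b <- function(bb) {
      tr <- marker_mean(p$lmm, bb, row, history$time_months)
      sum(stats::dnorm(history$sbp_mmhg, tr[, "sbp"],
                       p$lmm$sigma_eps[["sbp"]], log = TRUE)) +
        sum(stats::dnorm(history$dbp_mmhg, tr[, "dbp"],
                         p$lmm$sigma_eps[["dbp"]], log = TRUE)) +
        ld_mvnorm0(bb, p$lmm$Sigma) -
        cumulative_hazard(t_obs, p$hazard, p$lmm, row, bb)
    }
    step_sd <- sqrt(diag(p$lmm$Sigma)) /
      sqrt(1 + nrow(history) / c(4, 8, 4, 8))
    cur <- lp_b(b)
    for (s in seq_len(mh_steps)) {
      bc <- b + stats::rnorm(4, 0, step_sd)
      candidate <- lp_b(bc)
      if (log(stats::runif(1)) < candidate - cur) {
        b <- bc; cur <- candidate
      }
    }
    lam_t <- cumulative_hazard(t_obs, p$hazard, p$lmm, row, b)
    for (h in seq_len(nh)) {
      lam_u <- cumulative_hazard(horizons[h], p$hazard, p$lmm, row, b)
      S[j, h] <- exp(-(lam_u - lam_t))
    }
  }
  data.frame(horizon = horizons,
             mean = colMeans(S),
             lower = apply(S, 2, stats::quantile, 0.025),
             upper = apply(S, 2, stats::quantile, 0.975))
}
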