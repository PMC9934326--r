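ld_invgamma <- function(x, shape, rate) {
  # density of X with 1/X ~ Gamma(shape, rate), evaluated at x
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

ld_invwishart <- function(S, df, scale) {
  d <- nrow(S)
  ldet <- function(m) determinant(m, logarithm = TRUE)$modulus
  as.numeric(df / 2 * ldet(scale) - df * d / 2 * log(2) -
               sum(lgamma((df + 1 - seq_len(d)) / 2)) - d * (d - 1) / 4 * log(pi) -
               (df + d + 1) / 2 * ldet(S) -
               0.5 * sum(diag(solve(S, scale))))
}

#' Joint log prior density of the model parameters
#'
#' Longitudinal fixed effects, survival coefficients and baseline log-hazard
#' levels carry independent N(0, 1000) priors. The association coefficients
#' carry the global-local ridge shrinkage prior `rho_s ~ N(0, tau * psi_s)`
#' with `1/tau ~ Gamma(0.1, 0.1)` and `1/psi_s ~ Gamma(1, 0.01)` (hyperprior
#' terms evaluated on the precision scale on which they are stated). The
#' random-effect covariance has an inverse-Wishart(5, I) prior and the
#' residual variances inverse-gamma(0.01, 0.01).
#'
#' @param params a [joint_params()] object.
#' @return scalar log prior density.
#' @export
log_prior <- function(params) {
  stopifnot(inherits(params, "bp_joint_params"))
  sh <- params$shrinkage
  if (sh$tau <= 0 || any(sh$psi <= 0))
    stop("shrinkage scales must be strictly positive")
  mask <- association_mask(params$lmm$spec)
  coefs <- c(params$lmm$beta$sbp, params$lmm$beta$dbp,
             params$hazard$gamma, params$hazard$log_levels)
  lp <- sum(stats::dnorm(coefs, 0, sqrt(1000), log = TRUE))
  lp <- lp + sum(stats::dnorm(params$hazard$rho[mask], 0,
                              sqrt(sh$tau * sh$psi[mask]), log = TRUE))
  lp <- lp + stats::dgamma(1 / sh$tau, shape = 0.1, rate = 0.1, log = TRUE)
  lp <- lp + sum(stats::dgamma(1 / sh$psi[mask], shape = 1, rate = 0.01,
                               log = TRUE))
  lp <- lp + ld_invwishart(params$lmm$Sigma, 5, diag(4))
  lp <- lp + sum(ld_invgamma(params$lmm$sigma_eps^2, 0.01, 0.01))
  lp
}

#' Gibbs update of the global-local shrinkage hyperparameters
#'
#' Exact full-conditional draws under the ridge shrinkage prior: with `S`
#' association coefficients,
#' `1/tau ~ Gamma(0.1 + S/2, 0.1 + sum_s rho_s^2 / (2 psi_s))` and
#' `1/psi_s ~ Gamma(1 + 1/2, 0.01 + rho_s^2 / (2 tau))`.
#'
#' @param rho numeric vector of current association coefficients (the active
#'   components).
#' @param hypers current [shrinkage_hyper()] (supplies `psi` for the `tau`
#'   draw; its `psi` length must be at least `length(rho)`).
#' @return updated `bp_shrinkage` object.
#' @export
sample_shrinkage <- function(rho, hypers) {
  stopifnot(all(is.finite(rho)), inherits(hypers, "bp_shrinkage"))
  S <- length(rho)
  psi <- hypers$psi[seq_len(S)]
  tau_inv <- stats::rgamma(1, shape = 0.1 + S / 2,
                           rate = 0.1 + sum(rho^2 / (2 * psi)))
  tau <- 1 / tau_inv
  psi_inv <- stats::rgamma(S, shape = 1.5, rate = 0.01 + rho^2 / (2 * tau))
  out <- hypers
  out$tau <- tau
  out$psi[seq_len(S)] <- 1 / psi_inv
  out
}
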