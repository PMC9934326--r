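#' Split Gelman-Rubin convergence diagnostic
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor computed over the resulting half-chains, so within-chain trends
#' also inflate the statistic. Returns `NA` for constant parameters.
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return scalar R-hat (>= 1 up to numerical tolerance).
#' @export
rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  nn <- length(halves[[1]])
  if (nn < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of MCMC draws
#'
#' Combined-chain effective sample size from chain-averaged autocorrelations
#' with Geyer's initial-positive-sequence truncation.
#'
#' @param chains list of numeric vectors, one per chain.
#' @return scalar effective sample size (capped at the total draw count).
#' @export
ess <- function(chains) {
  m <- length(chains)
  nn <- length(chains[[1]])
  if (nn < 4) return(NA_real_)
  acfs <- vapply(chains, function(x) {
    if (stats::var(x) == 0) return(rep(NA_real_, nn))
    stats::acf(x, lag.max = nn - 1, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(nn))
  r <- rowMeans(acfs)
  if (anyNA(r)) return(NA_real_)
  # sum autocorrelations in lag pairs while each pair stays positive (Geyer)
  s <- 0
  k <- 2
  while (k + 1 <= length(r)) {
    pair <- r[k] + r[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  min(m * nn, m * nn / (1 + 2 * s))
}

summarize_chains <- function(draws) {
  pn <- colnames(draws[[1]])
  all <- do.call(rbind, draws)
  out <- data.frame(parameter = pn,
                    mean = colMeans(all),
                    sd = apply(all, 2, stats::sd),
                    q2.5 = apply(all, 2, stats::quantile, 0.025),
                    q97.5 = apply(all, 2, stats::quantile, 0.975),
                    rhat = NA_real_, ess = NA_real_, se = NA_real_,
                    row.names = NULL)
  for (j in seq_along(pn)) {
    ch <- lapply(draws, function(d) d[, j])
    if (isTRUE(stats::sd(all[, j]) > 0)) {
      out$rhat[j] <- rhat(ch)
      out$ess[j] <- ess(ch)
    }
  }
  out$se <- out$sd / sqrt(pmax(out$ess, 1))
  out
}

#' Deviance information criterion and WAIC of a joint fit
#'
#' Conditional (given the random effects) subject-level criteria from the
#' stored pointwise log-likelihood draws: DIC uses the deviance at the
#' posterior means of all parameters plus twice the effective number of
#' parameters `p_D = mean deviance - deviance at mean`; WAIC is
#' `-2 (lppd - p_waic)` with the variance-based `p_waic`.
#'
#' @param fit a `bp_joint_fit` from [run_mcmc()] (with stored pointwise
#'   log-likelihoods).
#' @return list with `dic`, `p_dic`, `waic`, `p_waic`, `lppd`, `deviance_at_mean`.
#' @export
model_fit_criteria <- function(fit) {
  pw <- fit$pointwise
  if (is.null(pw) || !nrow(pw))
    stop("fit carries no stored pointwise log-likelihood draws")
  dbar <- mean(-2 * rowSums(pw))
  dhat <- -2 * fit$loglik_at_mean
  p_dic <- dbar - dhat
  lse <- function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }
  lppd <- sum(apply(pw, 2, lse))
  p_waic <- sum(apply(pw, 2, stats::var))
  if (nrow(pw) == 1) p_waic <- 0
  list(dic = dhat + 2 * p_dic, p_dic = p_dic,
       waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd,
       deviance_at_mean = dhat)
}
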