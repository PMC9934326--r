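ld_mvnorm0 <- function(x, Sigma) {
  # log N(x; 0, Sigma) for a vector or the rows of a matrix
  ch <- chol(Sigma)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- backsolve(ch, t(x), transpose = TRUE)
  -0.5 * ncol(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Unnormalised log posterior of the joint model
#'
#' Sum of the longitudinal likelihood, the per-subject event-history
#' likelihood, the random-effect prior `N(b_i; 0, Sigma)` and [log_prior()].
#'
#' @param params a [joint_params()] object.
#' @param effects per-subject random-effect matrix (rows aligned with
#'   `data$baseline$id`).
#' @param data list with `baseline`, `longitudinal` and `survival` tables as
#'   produced by [generate_cohort()] or [read_tables()].
#' @return scalar unnormalised log posterior density.
#' @export
log_posterior <- function(params, effects, data) {
  stopifnot(inherits(params, "bp_joint_params"))
  n <- nrow(data$baseline)
  ll <- loglik_longitudinal(params$lmm, effects, data$longitudinal,
                            data$baseline)
  idx <- match(data$survival$id, data$baseline$id)
  if (anyNA(idx)) stop("survival ids missing from baseline table")
  for (k in seq_len(nrow(data$survival))) {
    i <- idx[k]
    ll <- ll + loglik_event(data$survival$time_months[k],
                            data$survival$event[k],
                            params$hazard, params$lmm,
                            data$baseline[i, , drop = FALSE],
                            effects[i, ])
  }
  if (n > 0) ll <- ll + sum(ld_mvnorm0(effects, params$lmm$Sigma))
  ll + log_prior(params)
}

#' Hazard-ratio summary of an association or survival coefficient
#'
#' Transforms a posterior sample (or point estimate) of a log hazard ratio
#' into the hazard-ratio scale with a central 95% interval and the percent
#' change in the remission rate per one-unit increase of the covariate or
#' marker value.
#'
#' @param coef numeric vector of posterior draws, or a single point
#'   estimate.
#' @param prob interval coverage (default 0.95).
#' @return list with `estimate` (posterior mean of the coefficient), `hr`,
#'   `lower`/`upper` (interval on the HR scale, NA for a point estimate),
#'   `percent` (absolute percent change) and `direction` (`"decrease"`,
#'   `"increase"` or `"none"`).
#' @export
#' @examples
#' hazard_ratio_summary(-0.1128) # HR 0.89, 10.67% decrease
hazard_ratio_summary <- function(coef, prob = 0.95) {
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  est <- mean(coef)
  hr <- exp(est)
  if (length(coef) > 1) {
    qs <- stats::quantile(coef, c((1 - prob) / 2, 1 - (1 - prob) / 2))
    lo <- exp(qs[[1]]); hi <- exp(qs[[2]])
  } else lo <- hi <- NA_real_
  pct <- if (hr < 1) 100 * (1 - hr) else 100 * (hr - 1)
  list(estimate = est, hr = hr, lower = lo, upper = hi,
       percent = pct,
       direction = if (hr < 1) "decrease" else if (hr > 1) "increase"
                   else "none")
}
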