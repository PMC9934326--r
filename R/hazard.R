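# Cached Gauss-Legendre rule on [-1, 1]; mapped affinely to each hazard
# segment. 15 points integrate the exp-linear integrands of this model to
# near machine precision per segment.
.bp_env <- new.env(parent = emptyenv())

gl_rule <- function(n = 15) {
  key <- paste0("gl", n)
  if (is.null(.bp_env[[key]]))
    .bp_env[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .bp_env[[key]]
}

# Index of the baseline-hazard interval containing each time.
interval_index <- function(t, knots) {
  pmin(pmax(findInterval(t, knots), 1L), length(knots))
}

# Linear-predictor coefficients of one subject's hazard:
# log h(t) = log_levels[k(t)] + const + slope * t, from the marker
# trajectories m(t) = intercept + slope_m * t entering via rho.
hazard_linpred <- function(hp, lmm, row, b) {
  m0 <- marker_mean(lmm, b, row, 0)
  sl <- marker_slope(lmm, b, row, 0)
  u <- build_design(row, 0, lmm$spec)$survival
  gam <- if (length(hp$gamma)) align_coef(hp$gamma, names(u), "survival")
         else numeric(0)
  rho <- unname(hp$rho)
  const <- sum(gam * u) +
    rho[1] * m0[1, "sbp"] + rho[2] * sl[1, "sbp"] +
    rho[3] * m0[1, "dbp"] + rho[4] * sl[1, "dbp"]
  slope <- rho[1] * sl[1, "sbp"] + rho[3] * sl[1, "dbp"]
  list(const = unname(const), slope = unname(slope))
}

#' Instantaneous hazard of first remission for one subject
#'
#' `h(t) = h0(t) exp(gamma'u + rho_1 m_sbp(t) + rho_2 m'_sbp(t) +
#' rho_3 m_dbp(t) + rho_4 m'_dbp(t))` with a piecewise-constant baseline
#' `h0`. Beyond the last knot the final baseline level is carried forward.
#'
#' @param t numeric vector of times, months (>= 0).
#' @param hp a [hazard_params()] object.
#' @param lmm a [lmm_params()] object describing the marker trajectories.
#' @param row single-row baseline data frame for the subject.
#' @param b length-4 random-effect vector.
#' @return vector of hazards (per month), strictly positive.
#' @export
hazard <- function(t, hp, lmm, row, b = numeric(4)) {
  stopifnot(inherits(hp, "bp_hazard_params"), is.numeric(t))
  if (any(t < 0)) stop("negative time in hazard()")
  lp <- hazard_linpred(hp, lmm, row, b)
  exp(hp$log_levels[interval_index(t, hp$knots)] + lp$const + lp$slope * t)
}

# Cumulative hazard for precomputed linear-predictor coefficients.
cumhaz_lp <- function(T, hp, const, slope, n_nodes = 15) {
  if (T <= 0) return(0)
  gl <- gl_rule(n_nodes)
  bounds <- c(hp$knots, Inf)
  total <- 0
  for (k in seq_along(hp$log_levels)) {
    a <- bounds[k]; bnd <- min(bounds[k + 1], T)
    if (bnd <= a) next
    half <- (bnd - a) / 2; mid <- (bnd + a) / 2
    tt <- mid + half * gl$x
    total <- total + half * sum(gl$w * exp(hp$log_levels[k] + const +
                                             slope * tt))
  }
  total
}

#' Cumulative hazard of first remission for one subject
#'
#' Integrates [hazard()] from 0 to `T` by fixed-order Gauss-Legendre
#' quadrature applied piecewise between the baseline-hazard knots, so the
#' integrand is smooth on every panel.
#'
#' @param T upper limit of integration, months (>= 0).
#' @inheritParams hazard
#' @param n_nodes quadrature order per knot interval.
#' @return scalar cumulative hazard, non-decreasing in `T`, 0 at `T = 0`.
#' @export
cumulative_hazard <- function(T, hp, lmm, row, b = numeric(4), n_nodes = 15) {
  stopifnot(length(T) == 1, is.numeric(T))
  if (T < 0) stop("negative time in cumulative_hazard()")
  lp <- hazard_linpred(hp, lmm, row, b)
  cumhaz_lp(T, hp, lp$const, lp$slope, n_nodes)
}

#' Event-history log-likelihood contribution of one subject
#'
#' `d * log h(T) - Lambda(T)` for observed exit time `T` and event indicator
#' `d` (1 = first remission observed, 0 = censored).
#'
#' @param time exit time, months.
#' @param event event indicator, 0 or 1.
#' @inheritParams hazard
#' @return scalar log-density contribution.
#' @export
loglik_event <- function(time, event, hp, lmm, row, b = numeric(4)) {
  stopifnot(length(time) == 1, length(event) == 1)
  if (time < 0) stop("negative event time")
  if (!event %in% c(0, 1)) stop("event indicator must be 0 or 1")
  lp <- hazard_linpred(hp, lmm, row, b)
  lh <- hp$log_levels[interval_index(time, hp$knots)] + lp$const +
    lp$slope * time
  event * lh - cumhaz_lp(time, hp, lp$const, lp$slope)
}
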