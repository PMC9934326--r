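#' Kaplan-Meier estimate of the remission-free curve
#'
#' Product-limit estimator (via [survival::survfit()]) with the median
#' survival time; with no censoring it equals the empirical survival
#' function.
#'
#' @param times non-negative event/censoring times, months.
#' @param events event indicators (1 = remission observed, 0 = censored).
#' @return object of class `bp_km`: data frame `curve` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, plus `median` (NA when not
#'   reached) and `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input to km_estimate()")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(if (is.list(q)) q$quantile else q)
  structure(list(curve = data.frame(time = fit$time,
                                    n_risk = fit$n.risk,
                                    n_event = fit$n.event,
                                    n_censor = fit$n.censor,
                                    surv = fit$surv),
                 median = med,
                 n = length(times)),
            class = "bp_km")
}

#' @export
print.bp_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, sum(x$curve$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test for equality of remission curves across groups
#'
#' Standard log-rank chi-square (via [survival::survdiff()]) with
#' `(groups - 1)` degrees of freedom.
#'
#' @param times non-negative event/censoring times.
#' @param events event indicators (0/1).
#' @param group group labels; at least two non-empty groups.
#' @return list with `statistic`, `df`, `p_value` and per-group
#'   observed/expected counts.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2)
    stop("log-rank test needs at least two non-empty groups")
  stopifnot(length(times) == length(events),
            length(times) == length(group))
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(fit$chisq),
       df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       observed = unname(fit$obs),
       expected = unname(fit$exp))
}
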