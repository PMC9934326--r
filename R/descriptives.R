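#' Pearson chi-square test of association for a contingency table
#'
#' Pearson's chi-square on the expected counts, with the Yates continuity
#' correction applied exactly when the table is 2x2 (the convention of the
#' reference analysis); larger tables are uncorrected.
#'
#' @param counts r x c matrix of non-negative integer counts with positive
#'   row and column sums.
#' @param correct apply the continuity correction? Default (`NULL`) applies
#'   it iff the table is 2x2.
#' @return object of class `bp_chisq` with `statistic`, `df`, `p_value`,
#'   `corrected` flag and the `expected` count table.
#' @export
#' @examples
#' chi_square_association(matrix(c(30, 28, 53, 190), 2))$statistic # 19.509
chi_square_association <- function(counts, correct = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0))
    stop(sprintf("row margin %d of the contingency table is zero",
                 which(rs == 0)[1]))
  if (any(cs == 0))
    stop(sprintf("column margin %d of the contingency table is zero",
                 which(cs == 0)[1]))
  if (is.null(correct)) correct <- all(dim(counts) == c(2, 2))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 corrected = correct && all(dim(counts) == c(2, 2)),
                 expected = ct$expected),
            class = "bp_chisq")
}

#' @export
print.bp_chisq <- function(x, ...) {
  cat(sprintf("Chi-square = %.4f, df = %d, p = %.4g%s\n", x$statistic, x$df,
              x$p_value,
              if (x$corrected) " (Yates-corrected)" else ""))
  invisible(x)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Baseline frequency table by censoring status, with association tests
#'
#' Cross-tabulates every categorical baseline covariate against
#' censored-vs-event status, reporting counts with percentages of the total
#' cohort (one decimal, half-up rounding) and the chi-square association
#' statistic per covariate; continuous covariates are summarised by mean and
#' SD.
#'
#' @param baseline baseline covariate table with column `id`.
#' @param surv survival table with columns `id`, `event`.
#' @return list with `categorical` (data frame: variable, category,
#'   censored/event/total counts and percentages, chi-square, df, p) and
#'   `continuous` (variable, mean, sd).
#' @export
baseline_summary <- function(baseline, surv) {
  if (!setequal(baseline$id, surv$id) ||
      nrow(baseline) != nrow(surv))
    stop("baseline and survival tables must carry the same subject ids")
  status <- factor(ifelse(surv$event[match(baseline$id, surv$id)] == 1,
                          "event", "censored"),
                   levels = c("censored", "event"))
  n <- nrow(baseline)
  cat_rows <- list()
  for (cov in intersect(names(covariate_levels()), names(baseline))) {
    tab <- table(factor(baseline[[cov]],
                        levels = covariate_levels()[[cov]]), status)
    test <- tryCatch(chi_square_association(as.matrix(unclass(tab))),
                     error = function(e) NULL)
    rows <- data.frame(variable = cov,
                       category = rownames(tab),
                       censored_n = as.integer(tab[, "censored"]),
                       censored_pct = round_half_up(
                         100 * tab[, "censored"] / n),
                       event_n = as.integer(tab[, "event"]),
                       event_pct = round_half_up(100 * tab[, "event"] / n),
                       total_n = as.integer(rowSums(tab)),
                       total_pct = round_half_up(100 * rowSums(tab) / n),
                       chisq = NA_real_, df = NA_integer_,
                       p_value = NA_real_,
                       row.names = NULL)
    if (!is.null(test)) {
      rows$chisq[1] <- test$statistic
      rows$df[1] <- test$df
      rows$p_value[1] <- test$p_value
    }
    cat_rows[[cov]] <- rows
  }
  cont <- intersect(continuous_covariates(), names(baseline))
  continuous <- data.frame(
    variable = cont,
    mean = vapply(cont, function(v) mean(baseline[[v]]), 0),
    sd = vapply(cont, function(v) stats::sd(baseline[[v]]), 0),
    row.names = NULL)
  list(categorical = do.call(rbind, c(cat_rows, make.row.names = FALSE)),
       continuous = continuous,
       n = n, n_event = sum(status == "event"),
       n_censored = sum(status == "censored"))
}

#' Required sample size for a survival study powered on a log hazard ratio
#'
#' `n = 4 (z_{alpha/2} + z_{power})^2 / (p * theta^2)` rounded up, where `p`
#' is the probability of the event and `theta` the log hazard ratio to be
#' detected.
#'
#' @param alpha two-sided significance level, in (0, 1).
#' @param power target power, in (0, 1).
#' @param p_event probability of the event, in (0, 1].
#' @param log_hr non-zero log hazard ratio.
#' @return smallest adequate integer sample size.
#' @export
#' @examples
#' required_sample_size(0.05, 0.80, 0.504, 0.4121) # 367
required_sample_size <- function(alpha, power, p_event, log_hr) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            p_event > 0, p_event <= 1)
  if (log_hr == 0)
    stop("log hazard ratio of zero implies an infinite sample size")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ceiling(4 * z^2 / (p_event * log_hr^2))
}
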