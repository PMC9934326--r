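#' Default category frequencies for the baseline covariates
#'
#' Exact count ratios (k/301) of the reference hypertension cohort, so each
#' covariate's probabilities sum to one exactly: 50.8% male, 58.8% urban,
#' 27.6% diabetes, 19.3% chronic kidney disease, 27.2% stroke, 8.3% HIV,
#' regimen 12.6/33.2/54.2% and drug type 34.2/28.2/25.6/12.0%.
#'
#' @return named list of named probability vectors.
#' @export
default_covariate_frequencies <- function() {
  list(sex = c(Female = 148, Male = 153) / 301,
       residence = c(Rural = 124, Urban = 177) / 301,
       dm = c(No = 218, Yes = 83) / 301,
       ckd = c(No = 243, Yes = 58) / 301,
       stroke = c(No = 219, Yes = 82) / 301,
       hiv = c(No = 276, Yes = 25) / 301,
       regimen = c(Monotherapy = 38, TwoDrug = 100, ThreeOrMore = 163) / 301,
       drug = c(Enalapril = 103, Nifedipine = 85, Both = 77, Others = 36) / 301)
}

#' Default moments and plausibility bounds for continuous baseline covariates
#'
#' Age uses the reference cohort's reported mean 51.77 and SD 13.88 years,
#' truncated at the inclusion minimum of 15 years. The laboratory covariates
#' are not reported in the source cohort; defaults sit at physiological
#' midpoints (cholesterol mg/dl, glucose mg/dl, BUN mg/dl, creatinine mg/dl,
#' serum electrolytes mmol/l, hemoglobin g/dl) and are fully configurable.
#'
#' @return named list; each element has `mean`, `sd`, `lower`, `upper`.
#' @export
default_covariate_moments <- function() {
  m <- function(mean, sd, lower, upper) list(mean = mean, sd = sd,
                                             lower = lower, upper = upper)
  list(age = m(51.77, 13.88, 15, 100),
       bcl = m(190, 35, 80, 400),
       gbl = m(110, 30, 40, 400),
       bun = m(15, 5, 2, 60),
       creatinine = m(0.9, 0.25, 0.2, 5),
       calcium = m(2.35, 0.15, 1.5, 3.5),
       sodium = m(140, 3, 120, 160),
       potassium = m(4.2, 0.4, 2.5, 7),
       chlorine = m(102, 3, 85, 120),
       hemoglobin = m(14, 1.5, 6, 20))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the reference registry cohort: 301 subjects, monthly
#' visits at 0..29 months, administrative censoring at the 30-month end of
#' the study window.
#'
#' @param n_subjects number of subjects (non-negative integer).
#' @param visit_schedule strictly increasing visit times in months, first at
#'   0.
#' @param admin_censor_time administrative censoring time, months; at least
#'   the last visit time.
#' @param covariate_frequencies named list of per-covariate category
#'   probability vectors (see [default_covariate_frequencies()]).
#' @param covariate_moments named list of continuous-covariate moments (see
#'   [default_covariate_moments()]).
#' @param dropout_rate optional exponential dropout hazard (per month) acting
#'   in addition to administrative censoring; 0 disables dropout.
#' @param seed optional integer seed used by [generate_cohort()] when no seed
#'   is passed there.
#' @return object of class `bp_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 301,
                          visit_schedule = 0:29,
                          admin_censor_time = 30,
                          covariate_frequencies = default_covariate_frequencies(),
                          covariate_moments = default_covariate_moments(),
                          dropout_rate = 0,
                          seed = NULL) {
  stopifnot(length(n_subjects) == 1, n_subjects >= 0,
            n_subjects == round(n_subjects))
  if (length(visit_schedule) == 0) stop("visit schedule must be non-empty")
  if (visit_schedule[1] != 0) stop("first visit must be at time 0")
  if (any(diff(visit_schedule) <= 0))
    stop("visit schedule must be strictly increasing")
  if (admin_censor_time < max(visit_schedule))
    stop("admin_censor_time must be at least the last visit time")
  for (cov in names(covariate_frequencies)) {
    p <- covariate_frequencies[[cov]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(sprintf("invalid probability vector for covariate '%s'", cov))
    lv <- covariate_levels()[[cov]]
    if (!is.null(lv) && !identical(names(p), lv))
      stop(sprintf("categories for covariate '%s' must be %s", cov,
                   paste(lv, collapse = ", ")))
  }
  stopifnot(dropout_rate >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_schedule = as.numeric(visit_schedule),
                 admin_censor_time = admin_censor_time,
                 covariate_frequencies = covariate_frequencies,
                 covariate_moments = covariate_moments,
                 dropout_rate = dropout_rate,
                 seed = seed),
            class = "bp_cohort_config")
}
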