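# Canonical covariate schema of the baseline table. Categorical covariates
# use reference-cell coding; the first level is the reference (Female, Rural,
# "No" for comorbidity history, Monotherapy, Enalapril).
covariate_levels <- function() {
  list(sex = c("Female", "Male"),
       residence = c("Rural", "Urban"),
       dm = c("No", "Yes"),
       ckd = c("No", "Yes"),
       stroke = c("No", "Yes"),
       hiv = c("No", "Yes"),
       regimen = c("Monotherapy", "TwoDrug", "ThreeOrMore"),
       drug = c("Enalapril", "Nifedipine", "Both", "Others"))
}

continuous_covariates <- function() {
  c("age", "bcl", "gbl", "bun", "creatinine", "calcium", "sodium",
    "potassium", "chlorine", "hemoglobin")
}

# Design-column names a covariate expands to under reference-cell coding.
expanded_names <- function(cov) {
  lv <- covariate_levels()
  if (cov %in% names(lv)) paste0(cov, lv[[cov]][-1]) else cov
}

# Expand the named baseline covariates of `data` into a numeric design matrix
# (no intercept, no time column). Unknown covariates or categories error.
covariate_matrix <- function(data, covs) {
  n <- nrow(data)
  lv <- covariate_levels()
  cols <- list()
  for (cov in covs) {
    if (!cov %in% names(data))
      stop(sprintf("covariate '%s' not found in baseline table", cov))
    x <- data[[cov]]
    if (cov %in% names(lv)) {
      x <- as.character(x)
      bad <- !(x %in% lv[[cov]]) & !is.na(x)
      if (any(bad))
        stop(sprintf("unknown category '%s' for covariate '%s'",
                     x[which(bad)[1]], cov))
      for (l in lv[[cov]][-1])
        cols[[paste0(cov, l)]] <- as.numeric(x == l)
    } else {
      if (!is.numeric(x))
        stop(sprintf("covariate '%s' must be numeric", cov))
      cols[[cov]] <- as.numeric(x)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  rownames(m) <- NULL
  m
}

#' Build design rows for one subject at one time
#'
#' Expands a subject's baseline covariates into the fixed-effect design row of
#' each marker (intercept, time, then reference-cell-coded covariates), the
#' random-effect design `Z = (1, t)`, and the survival covariate row.
#'
#' @param row a single-row data frame with the subject's baseline covariates.
#' @param time time since enrolment, months.
#' @param spec a [design_spec()].
#' @return list with components `sbp`, `dbp` (named fixed-design vectors),
#'   `Z = c(1, time)` and `survival` (named covariate vector for the hazard).
#' @export
#' @examples
#' row <- data.frame(sex = "Male", residence = "Urban", age = 50)
#' build_design(row, 3, design_spec(sbp = c("age", "residence"),
#'                                  dbp = "age", survival = "sex"))
build_design <- function(row, time, spec = design_spec()) {
  stopifnot(is.data.frame(row), nrow(row) == 1, is.numeric(time),
            length(time) == 1)
  fixed_row <- function(covs) {
    m <- covariate_matrix(row, covs)
    stats::setNames(c(1, time, as.numeric(m[1, ])),
                    c("(Intercept)", "time", colnames(m)))
  }
  u <- covariate_matrix(row, spec$survival)
  list(sbp = fixed_row(spec$sbp),
       dbp = fixed_row(spec$dbp),
       Z = c(1, time),
       survival = stats::setNames(as.numeric(u[1, ]), colnames(u)))
}

# Align a named coefficient vector with design columns, erroring on mismatch.
align_coef <- function(beta, cols, what) {
  if (length(beta) != length(cols) || !all(cols %in% names(beta)))
    stop(sprintf("%s coefficients do not match design columns (%s vs %s)",
                 what, paste(names(beta), collapse = ","),
                 paste(cols, collapse = ",")))
  beta[cols]
}
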