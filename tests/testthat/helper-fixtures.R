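# Shared fixtures: minimal design specs and parameter sets used across tests.

# A one-covariate design so single-row fixtures stay small.
tiny_spec <- function() {
  design_spec(sbp = "age", dbp = "age", survival = "sex")
}

# Zero-effect longitudinal parameters (markers identically zero, unit noise).
zero_lmm <- function(spec = tiny_spec(), sigma_eps = c(1, 1),
                     Sigma = diag(4) * 0) {
  beta <- c("(Intercept)" = 0, time = 0, age = 0)
  lmm_params(beta, beta, Sigma, sigma_eps, spec = spec)
}

# Constant-hazard survival parameters with no covariate or marker link.
const_hazard <- function(h0 = 0.1, spec = tiny_spec()) {
  hazard_params(log(h0), 0,
                gamma = stats::setNames(0, expanded_names_pub(spec$survival[1])),
                rho = numeric(4))
}

# expanded_names is internal; reproduce the reference-cell column names.
expanded_names_pub <- function(cov) {
  lv <- list(sex = c("Female", "Male"), residence = c("Rural", "Urban"),
             dm = c("No", "Yes"), ckd = c("No", "Yes"),
             stroke = c("No", "Yes"), hiv = c("No", "Yes"),
             regimen = c("Monotherapy", "TwoDrug", "ThreeOrMore"),
             drug = c("Enalapril", "Nifedipine", "Both", "Others"))
  if (cov %in% names(lv)) paste0(cov, lv[[cov]][-1]) else cov
}

# A reference-subject row: all categorical covariates at their reference
# level, all continuous covariates at zero.
reference_row <- function(id = 1) {
  data.frame(id = id, sex = "Female", residence = "Rural", age = 0,
             bcl = 0, gbl = 0, bun = 0, creatinine = 0, calcium = 0,
             sodium = 0, potassium = 0, chlorine = 0, hemoglobin = 0,
             dm = "No", ckd = "No", stroke = "No", hiv = "No",
             regimen = "Monotherapy", drug = "Enalapril",
             stringsAsFactors = FALSE)
}

# Contingency tables of the reference cohort's Table of baseline factors
# vs censoring status (censored column first).
reference_tables <- function() {
  list(sex = matrix(c(30, 28, 123, 120), 2),
       residence = matrix(c(33, 25, 144, 99), 2),
       dm = matrix(c(30, 28, 53, 190), 2),
       ckd = matrix(c(16, 42, 42, 201), 2),
       stroke = matrix(c(25, 33, 57, 186), 2),
       hiv = matrix(c(9, 49, 16, 227), 2),
       regimen = matrix(c(6, 20, 32, 32, 80, 131), 3),
       drug = matrix(c(20, 13, 19, 6, 83, 72, 58, 30), 4))
}

# Small joint dataset drawn from simple truth, for likelihood oracles.
tiny_joint_data <- function(n = 4, seed = 99) {
  spec <- tiny_spec()
  beta1 <- c("(Intercept)" = 120, time = -0.5, age = 0.2)
  beta2 <- c("(Intercept)" = 80, time = -0.3, age = 0.1)
  lmm <- lmm_params(beta1, beta2,
                    sigma_from_sd_corr(c(8, 0.5, 5, 0.3), diag(4)),
                    c(10, 6), spec = spec)
  hz <- hazard_params(log(0.08), 0, gamma = c(sexMale = -0.3),
                      rho = c(-0.02, 0, 0.01, 0))
  truth <- joint_params(lmm, hz)
  cfg <- cohort_config(n_subjects = n, visit_schedule = c(0, 2, 5, 9),
                       admin_censor_time = 12)
  generate_cohort(cfg, truth, seed = seed)
}
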