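---
title: "Joint modelling of blood pressure trajectories and time to remission: methods"
author: "bpjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of blood pressure trajectories and time to remission: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpjoint)
```

## The model

`bpjoint` implements a shared-parameter joint model for a hypertensive
cohort followed over roughly monthly clinic visits. Two processes are
modelled together:

**Longitudinal submodel.** The observed systolic and diastolic pressures of
subject $i$ at visit time $t_{ij}$ (months since enrolment) are

$$Y_{ij}^{(m)} = m_i^{(m)}(t_{ij}) + \varepsilon_{ij}^{(m)}, \qquad
  \varepsilon_{ij}^{(m)} \sim N(0, \sigma_m^2), \quad m \in \{\text{SBP},
  \text{DBP}\},$$

where the true (noise-free) trajectory is linear in time,

$$m_i^{(m)}(t) = x_i'\beta_m + a_{im} + b_{im}\, t,$$

with fixed effects $\beta_m$ over an intercept, time, and baseline
covariates (reference-cell coded), and subject-specific random intercepts
and slopes. The stacked random effect
$b_i = (a_{i1}, b_{i1}, a_{i2}, b_{i2})' \sim N(0, \Sigma)$ with an
unstructured $4\times4$ covariance, so the two pressures are correlated both
at baseline and in their rates of change. Residuals are independent across
visits and markers given $b_i$; no serial correlation beyond the random
effects is modelled.

**Survival submodel.** The hazard of first remission (first attainment of
controlled blood pressure; later rises do not undo the event) is

$$h_i(t) = h_0(t)\exp\!\big[\gamma' u_i + \rho_1 m_i^{(1)}(t) + \rho_2
  \dot m_i^{(1)}(t) + \rho_3 m_i^{(2)}(t) + \rho_4 \dot m_i^{(2)}(t)\big],$$

the *current value and slope* association: the hazard at $t$ depends on each
marker's true level and rate of change at $t$. $u_i$ are time-invariant
covariates (default: sex, age, diabetes history, drug type) and $h_0$ is
piecewise constant on intervals whose knots sit at event-time quantiles of
the fitted data (5 intervals by default). Beyond the last knot the final
level is carried forward. $\exp(\rho_1)$ is the hazard ratio per 1 mmHg of
current systolic pressure.

Under the linear time trend the marginal (random effects integrated out)
covariance of the two observed pressures at time $t$ has the closed form
used by `marginal_covariance()`: per marker pair,
$z' \Sigma_{\text{block}} z$ with $z = (1, t)'$, plus residual variance on
the diagonal. Evaluated at the reported random-effect SDs
(10.8131, 0.8605, 6.7399, 0.5223), their correlations, and residual SDs
(15.0348, 9.5268), the implied SBP–DBP correlation is
`r round(marginal_covariance(default_truth()$lmm, 0)$correlation, 4)` at the
first visit and
`r round(marginal_covariance(default_truth()$lmm, 1)$correlation, 4)` one
month later. Under strictly monthly visits the third visit ($t = 2$) gives
about 0.236, slightly below the 0.244 sometimes quoted for a third visit;
the visit timing behind that figure is not recoverable, so the package
makes no claim about it.

## Priors

- Longitudinal fixed effects, survival coefficients $\gamma$, and baseline
  log-hazard levels: independent $N(0, 1000)$.
- Association coefficients: a global–local ridge shrinkage prior,
  $\rho_s \sim N(0, \tau\psi_s)$ with $\tau^{-1} \sim \text{Gamma}(0.1, 0.1)$
  and $\psi_s^{-1} \sim \text{Gamma}(1, 0.01)$. The global scale $\tau$
  pulls all association coefficients toward zero; the local $\psi_s$ let
  individual coefficients escape.
- Where the model needs priors beyond those stated above, weakly
  informative conjugate defaults in the same spirit are used:
  $\Sigma \sim \text{inverse-Wishart}(5, I_4)$,
  $\sigma_m^2 \sim \text{inverse-gamma}(0.01, 0.01)$.

## Posterior computation

`run_mcmc()` is a Metropolis-within-Gibbs sampler over the blocks:

1. **Longitudinal fixed effects** — given $(b_i, \sigma_m)$ the
   longitudinal likelihood times the Gaussian prior has a closed-form
   Gaussian conditional. When the marker is linked to the hazard
   ($\rho \ne 0$ for that marker) this conditional is not the full
   conditional, so the update is an autoregressive (Crank–Nicolson) step
   around it: the proposal leaves the Gaussian part invariant and the
   Metropolis ratio reduces to the survival-likelihood ratio, with the step
   size adapted toward 44% acceptance during burn-in. When the marker is
   unlinked the step is the exact Gibbs draw.
2. **Random effects** — one 4-dimensional random-walk Metropolis update per
   subject, vectorised across subjects, with per-subject proposal scales
   built from the longitudinal information matrix and adapted toward 23.4%
   acceptance.
3. **Variance components** — exact conjugate draws
   (inverse-gamma residual variances, inverse-Wishart $\Sigma$).
4. **Survival block** ($\log h_0$ levels, $\gamma$, active $\rho$) — joint
   adaptive random-walk Metropolis with the Haario empirical-covariance
   proposal, mixed with a 5% fixed-scale component so the proposal cannot
   collapse; repeated `surv_reps` (default 5) times per scan since this is
   the slowest-mixing block. Initial values come from a Cox fit and
   piecewise-exponential rates.
5. **Shrinkage hyperparameters** — exact conjugate gamma draws
   (`sample_shrinkage()`), which are the full conditionals stated above.

Two numerical choices matter. First, the cumulative hazard
$\Lambda_i(t)$ is computed by 15-point Gauss–Legendre quadrature applied
piecewise between the baseline knots, so the integrand
($e^{\text{linear in } t}$ per panel) is smooth on every panel; against the
available closed forms the error is below $10^{-10}$. Second, inside the
sampler the marker values entering the hazard are centred at the cohort
mean pressures, $\rho'(m_i(t) - c)$. With uncentred markers
$\rho_1 \bar m \approx -17$, so the baseline log-levels and $\rho$ would sit
on a near-degenerate posterior ridge spanning ~17 log-units; centring is a
pure reparameterisation (reported baseline levels are transformed back) that
removes the ridge. Adaptation runs only during burn-in; all randomness
derives from one master seed (chain $c$ uses `seed + 1009*(c-1)`), making
every fit bit-reproducible.

Defaults are 3 chains of 20,000 iterations (half burn-in, thinned by 10).
Convergence is summarised per parameter by split-$\widehat R$ and an
effective sample size with Geyer initial-positive-sequence truncation;
parameters with $\widehat R > 1.1$ are flagged in `$not_converged`. The
summary reports both the posterior SD and a time-series standard error
(SD/$\sqrt{\text{ESS}}$); published per-parameter "SE" columns of this kind
of analysis are of the second kind, and the two should not be conflated.

Model comparison uses conditional (given $b_i$) subject-level DIC and WAIC
from stored pointwise log-likelihood draws. These are the standard
substitutes here for decomposition-based information criteria that depend
on formulas external to this package.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with exactly the statistical structure the
analysis assumes, so every downstream stage is testable without patient
data. Its defaults emulate the reference registry cohort of 301 hypertensive
outpatients followed for 30 months:

- **Baseline covariates.** Categorical frequencies are the cohort's exact
  count ratios (50.8% male, 58.8% urban, 27.6% diabetes, 19.3% CKD, 27.2%
  stroke, 8.3% HIV, regimen 12.6/33.2/54.2%, drug type
  34.2/28.2/25.6/12.0%). Age is truncated normal with mean 51.77, SD 13.88,
  minimum 15 years (the inclusion criterion). The laboratory covariates'
  moments are not reported anywhere, so defaults sit at physiological
  midpoints (e.g. sodium 140 ± 3 mmol/l, calcium 2.35 ± 0.15 mmol/l,
  hemoglobin 14 ± 1.5 g/dl); with these, the implied mean baseline SBP/DBP
  (≈149/90 mmHg) is close to the reported 152.18/92.79 mmHg, which supports
  the chosen units and midpoints. All moments are configurable.
- **Visit schedule.** The source registry's visit spacing is not stated;
  monthly visits at $t = 0, 1, \ldots, 29$ are assumed, with the first visit
  at enrolment ($t = 0$) — the convention under which the first-visit
  marginal correlation 0.260 reproduces. Administrative censoring is at 30
  months (the length of the study window).
- **Trajectories and events.** Fixed effects, $\Sigma$ and residual SDs
  default to the fitted posterior means of the reference analysis; survival
  coefficients use the reported hazard ratios (male 0.63, age 0.9987,
  diabetes 0.54, "other" treatment 1.76) and the association defaults to
  the reported value-of-SBP coefficient −0.1128. Event times are drawn by
  inverting each subject's cumulative hazard at a uniform draw (bracketed
  root finding), i.e. from the model under study — not by thresholding the
  simulated pressures below 140/90. That choice is deliberate: parameter
  recovery must exercise the implemented hazard model; a threshold-crossing
  `controlled` flag is still emitted per visit as a diagnostic. The baseline
  log-hazard levels (13.86 − 0.16 per 6-month interval, on the uncentred
  scale) were calibrated once, by simulation, so the defaults reproduce the
  cohort's event pattern — median time to first remission near 11 months and
  roughly 19% censored — and then frozen.
- **Dropout.** None by default (the source reports only administrative
  censoring); an exponential dropout rate is available in the
  configuration.

What the generator does **not** emulate: irregular or missed visits,
measurement rounding to clinic precision, informative dropout, and any
misspecification of the linear time trend. Passing recovery tests on these
cohorts therefore demonstrates the correctness of the implementation under
the model's own assumptions, not robustness of the model on real registry
data.

## Descriptive layer and design conventions

`chi_square_association()` applies Pearson's test with the Yates continuity
correction exactly when a table is 2×2 — the convention that reproduces
every printed association statistic of the reference cohort's baseline
table — and exposes the correction as a flag. Percentages are formatted to
one decimal with half-up rounding, mirroring that table.
`required_sample_size()` implements
$n = 4(z_{\alpha/2} + z_{\beta})^2 / (p\,\theta_R^2)$; at the reference
inputs ($\alpha = 0.05$, power 80%, $p = 0.504$, $\theta_R = 0.4121$) it
returns 367. The reference study nevertheless enrolled 301 subjects; the
discrepancy is in the source, not in the formula, and 301 is used here only
as the default cohort size.

Reference categories follow the descriptive table (female, rural, no
comorbidity, monotherapy, enalapril); where the source's coding table
conflicts with the fitted-model row labels (e.g. "Urban = 0" vs a printed
urban coefficient), the fitted-model labels win, since they are what the
default truth parameters attach to.

Which covariates enter each marker is exactly the set the fitted model
reports per marker (SBP includes diabetes/stroke/creatinine; DBP includes
sodium and chlorine instead), configurable via `design_spec()`. The
association structure is value+slope for both markers by default, with
value-only and slope-only variants available. Which covariates entered the
published survival submodel is only partly recoverable (sex, age, diabetes,
treatment type are reported); that set is the default and is configurable.

## Problem sizes used in the test suite

The shipped tests exercise the full pipeline at sizes chosen to make
sampling error negligible where a tight bound is asserted (50,000 draws for
covariance recovery, 5,000 subjects for Kaplan–Meier convergence) and to
keep the end-to-end recovery experiment at the reduced reference setting:
300 subjects, truth at the fitted posterior means with association
(−0.11, 0, 0, 0), two chains of 4,000 iterations. At that setting ≥90% of
the longitudinal fixed effects land within 3 posterior SDs of truth and the
95% credible interval for the value-of-SBP association covers it; a few
parameters still flag $\widehat R > 1.1$, which disappears at the default
3 × 20,000 setting.

## Known limitations

- A linear time trend per marker; no splines or serial correlation.
- Only first remission; no competing risks or recurrent events.
- Exogenous time-varying covariates cannot enter the hazard.
- Conditional DIC/WAIC (given random effects) are reported; marginal
  versions would require integrating $b_i$ out.
- The random-effect Metropolis block conditions on one subject at a time;
  for cohorts with very few visits per subject, mixing of $\Sigma$ can be
  slow and longer chains are advisable.
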