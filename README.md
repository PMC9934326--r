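# bpjoint

Bayesian joint modelling of bivariate longitudinal blood pressure (systolic
and diastolic, mmHg) and time to first remission of hypertension.

Hypertension management studies follow outpatients over repeated clinic
visits, recording SBP/DBP at each visit and the time until blood pressure
first comes under control ("first remission"). Analysing the trajectories
and the event times separately discards the information that links them:
patients whose true pressure is high, or falling slowly, reach remission
later. `bpjoint` implements the shared-parameter joint model for this
setting, for biostatisticians who want a fully Bayesian, reproducible
pipeline from cohort simulation through MCMC fitting to dynamic prediction.

## The model

A bivariate linear mixed submodel for the markers,

    Y_ij(t) = m_i(t) + eps_ij,   m_i(t) = x_i' beta + a_i + b_i t,
    (a_i1, b_i1, a_i2, b_i2) ~ N(0, Sigma),  eps ~ N(0, sigma_m^2),

linked to a proportional-hazards submodel through the current true value
and slope of each marker,

    h_i(t) = h0(t) exp[ gamma' u_i + rho_1 m_i1(t) + rho_2 m_i1'(t)
                                   + rho_3 m_i2(t) + rho_4 m_i2'(t) ],

with piecewise-constant h0 and a global–local ridge shrinkage prior on the
association coefficients: `rho_s ~ N(0, tau psi_s)`,
`1/tau ~ Gamma(0.1, 0.1)`, `1/psi_s ~ Gamma(1, 0.01)`. Fixed effects and
survival coefficients have N(0, 1000) priors. Inference is by a
Metropolis-within-Gibbs sampler (conjugate draws where they exist, adaptive
Metropolis elsewhere); see the methods vignette
(`vignettes/bpjoint-methods.Rmd`) for the full account.

The package also ships the surrounding analysis layer: a synthetic cohort
generator calibrated to a reference hypertension registry (n = 301, monthly
visits, 30-month window), Kaplan–Meier and log-rank descriptives,
contingency chi-square tests (Yates-corrected for 2×2), the survival
sample-size formula, convergence diagnostics, DIC/WAIC, and dynamic
prediction of conditional remission-free probability.

## Worked example

```r
library(bpjoint)

coh <- generate_cohort(cohort_config(), seed = 42)   # 301 subjects
km  <- km_estimate(coh$survival$time_months, coh$survival$event)
km
#> Kaplan-Meier curve: n = 301, events = 237, median = 9.823707 months

marginal_covariance(coh$truth$lmm, 0)$correlation
#> [1] 0.2603319

fit <- run_mcmc(coh, mcmc_control(chains = 2, iter = 4000,
                                  burnin = 2000, thin = 10), seed = 1)
fit
#> Bayesian joint fit: 2 chains x 4000 iterations (burn-in 2000, thin 10)
#> 63 parameters; 25 flagged R-hat > 1.1
#> mean acceptance: sbp-beta 0.42, dbp-beta 0.93, b 0.24, survival 0.21

subset(fit$summary, parameter %in%
       c("sbp:time", "dbp:time", "assoc:value_sbp"))[, 1:5]
#>        parameter    mean       sd    q2.5    q97.5
#>         sbp:time -0.7600  0.06915 -0.8840 -0.61491
#>         dbp:time -0.6213  0.05014 -0.7224 -0.52024
#>  assoc:value_sbp -0.1145  0.01360 -0.1425 -0.08802

hr <- hazard_ratio_summary(do.call(rbind, fit$draws)[, "assoc:value_sbp"])
#> value-SBP association: HR 0.892 (0.867, 0.916), 10.82% decrease per mmHg
```

The cohort was generated with a true value-of-SBP association of −0.1128;
the reduced two-chain fit recovers it (posterior mean −0.1145, 95% CI
−0.143 to −0.088): each 1 mmHg of current systolic pressure lowers the
remission hazard by about 11%. The marker slopes (−0.76 and −0.62
mmHg/month against truths −0.84 and −0.62) show blood pressure falling
under treatment. At these reduced settings some parameters still flag
R-hat > 1.1; the default `mcmc_control()` (3 × 20,000) resolves this.

A command-line driver mirrors the R API:

```sh
exec/bpjoint simulate --config cfg.yaml --seed 42 --out data/
exec/bpjoint describe --baseline data/baseline.csv --surv data/survival.csv --out table.csv
exec/bpjoint km --surv data/survival.csv --baseline data/baseline.csv --group sex --out km.csv
exec/bpjoint fit --long data/longitudinal.csv --surv data/survival.csv \
                 --baseline data/baseline.csv --seed 1 --out fit/
```

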