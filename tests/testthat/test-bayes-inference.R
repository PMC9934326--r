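test_that("log prior matches a term-by-term oracle", {
  set.seed(31)
  spec <- tiny_spec()
  beta1 <- c("(Intercept)" = rnorm(1), time = rnorm(1), age = rnorm(1))
  beta2 <- c("(Intercept)" = rnorm(1), time = rnorm(1), age = rnorm(1))
  A <- matrix(rnorm(16), 4); Sigma <- crossprod(A) + diag(4)
  sig <- c(1.3, 0.8)
  lmm <- lmm_params(beta1, beta2, Sigma, sig, spec = spec)
  hp <- hazard_params(c(-1.1, -0.4), c(0, 5), gamma = c(sexMale = 0.7),
                      rho = rnorm(4, 0, 0.1))
  sh <- shrinkage_hyper(tau = 0.5, psi = c(0.02, 0.01, 0.05, 0.3))
  p <- joint_params(lmm, hp, sh)
  lp <- log_prior(p)
  norm_terms <- sum(dnorm(c(beta1, beta2, hp$gamma, hp$log_levels), 0,
                          sqrt(1000), log = TRUE)) +
    sum(dnorm(hp$rho, 0, sqrt(sh$tau * sh$psi), log = TRUE))
  hyper <- dgamma(1 / sh$tau, 0.1, rate = 0.1, log = TRUE) +
    sum(dgamma(1 / sh$psi, 1, rate = 0.01, log = TRUE))
  # inverse-Wishart(5, I) density at Sigma
  d <- 4; df <- 5
  iw <- df / 2 * 0 - df * d / 2 * log(2) -
    sum(lgamma((df + 1 - 1:d) / 2)) - d * (d - 1) / 4 * log(pi) -
    (df + d + 1) / 2 * determinant(Sigma)$modulus -
    0.5 * sum(diag(solve(Sigma)))
  ig <- sum(0.01 * log(0.01) - lgamma(0.01) - 1.01 * log(sig^2) -
              0.01 / sig^2)
  expect_equal(lp, norm_terms + hyper + as.numeric(iw) + ig,
               tolerance = 1e-10)
  # doubling a coefficient from 0 to k lowers the Gaussian term by k^2/2000
  p2 <- p; p2$lmm$beta$sbp["age"] <- 0
  p3 <- p2; p3$lmm$beta$sbp["age"] <- 3
  expect_equal(log_prior(p2) - log_prior(p3), 9 / 2000, tolerance = 1e-9)
  bad <- p; bad$shrinkage$tau <- -1
  expect_error(log_prior(bad), "positive")
})

test_that("shrinkage Gibbs draws match their gamma full conditionals", {
  set.seed(55)
  draws_tau <- replicate(1e5,
    1 / sample_shrinkage(rep(0, 4), shrinkage_hyper())$tau)
  expect_equal(mean(draws_tau), (0.1 + 2) / 0.1, tolerance = 0.02)
  set.seed(56)
  draws_psi <- replicate(2e4,
    1 / sample_shrinkage(0, shrinkage_hyper())$psi[1])
  expect_equal(mean(draws_psi), 1.5 / 0.01, tolerance = 0.02)
  set.seed(99); a <- sample_shrinkage(c(0.1, -0.2), shrinkage_hyper())
  set.seed(99); b <- sample_shrinkage(c(0.1, -0.2), shrinkage_hyper())
  expect_identical(a, b)
})

test_that("log posterior equals the sum of its component oracles", {
  coh <- tiny_joint_data(n = 4)
  params <- joint_params(coh$truth$lmm, coh$truth$hazard)
  dat <- coh[c("baseline", "longitudinal", "survival")]
  lp <- log_posterior(params, coh$effects, dat)
  ll_long <- loglik_longitudinal(params$lmm, coh$effects, coh$longitudinal,
                                 coh$baseline)
  ll_ev <- sum(vapply(seq_len(4), function(i) {
    loglik_event(coh$survival$time_months[i], coh$survival$event[i],
                 params$hazard, params$lmm,
                 coh$baseline[i, , drop = FALSE], coh$effects[i, ])
  }, 0))
  ch <- chol(params$lmm$Sigma)
  ll_b <- sum(vapply(seq_len(4), function(i) {
    z <- backsolve(ch, coh$effects[i, ], transpose = TRUE)
    -2 * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
  }, 0))
  expect_equal(lp, ll_long + ll_ev + ll_b + log_prior(params),
               tolerance = 1e-8)
  # moving one observation away from its mean can only lower the posterior
  worse <- dat
  worse$longitudinal$sbp_mmhg[1] <- worse$longitudinal$sbp_mmhg[1] + 1e4
  expect_lt(log_posterior(params, coh$effects, worse), lp)
})

test_that("hazard-ratio transform reports HR and percent change", {
  hr <- hazard_ratio_summary(-0.1128)
  expect_equal(round(hr$hr, 2), 0.89)
  expect_equal(round(hr$percent, 2), 10.67)
  expect_equal(hr$direction, "decrease")
  none <- hazard_ratio_summary(0)
  expect_equal(none$hr, 1)
  expect_equal(none$percent, 0)
  set.seed(3)
  draws <- rnorm(4000, 0.3, 0.05)
  hs <- hazard_ratio_summary(draws)
  expect_equal(hs$hr, exp(mean(draws)))
  expect_lt(hs$lower, hs$hr); expect_gt(hs$upper, hs$hr)
  expect_equal(hs$direction, "increase")
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(21)
  iid <- lapply(1:3, function(i) rnorm(500))
  expect_lt(abs(rhat(iid) - 1), 0.02)
  expect_gt(ess(iid), 0.5 * 1500)
  apart <- lapply(1:3, function(i) rnorm(500, mean = 10 * i))
  expect_gt(rhat(apart), 2)
  # strongly autocorrelated chain has far fewer effective draws
  ar <- lapply(1:3, function(i) {
    x <- numeric(500)
    for (k in 2:500) x[k] <- 0.95 * x[k - 1] + rnorm(1)
    x
  })
  expect_lt(ess(ar), 300)
  # independent cross-check against coda on a single chain
  expect_equal(ess(list(iid[[1]])),
               unname(coda::effectiveSize(coda::mcmc(iid[[1]]))),
               tolerance = 0.25)
})

test_that("MCMC is seed-reproducible and flags inconsistent inputs", {
  coh <- generate_cohort(cohort_config(n_subjects = 40), seed = 9)
  ctl <- mcmc_control(chains = 2, iter = 200, burnin = 100, thin = 5)
  f1 <- run_mcmc(coh, ctl, seed = 77)
  f2 <- run_mcmc(coh, ctl, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws[[1]], f1$draws[[2]]))
  bad <- coh[c("baseline", "longitudinal", "survival")]
  bad$survival <- bad$survival[-1, ]
  expect_error(run_mcmc(bad, ctl, seed = 1), "inconsistent ids")
  allc <- coh[c("baseline", "longitudinal", "survival")]
  allc$survival$event <- 0
  expect_error(run_mcmc(allc, ctl, seed = 1), "no events")
})

test_that("joint and separate longitudinal estimates agree when unlinked", {
  # with the association inactive the longitudinal block is a pure mixed
  # model, so posterior means should track a likelihood-based fit
  truth <- default_truth()
  truth$hazard$rho[] <- 0
  # with the marker link removed, set a plain moderate baseline hazard
  truth$hazard$log_levels[] <- log(0.05)
  coh <- generate_cohort(cohort_config(n_subjects = 120), truth, seed = 31)
  fit <- run_mcmc(coh, mcmc_control(chains = 2, iter = 1200, burnin = 600,
                                    thin = 5), seed = 4)
  s <- fit$summary
  lme_fit <- suppressWarnings(lme4::lmer(
    sbp_mmhg ~ time_months + age + residence + bcl + bun + creatinine +
      calcium + hemoglobin + dm + ckd + stroke + hiv + drug +
      (1 + time_months | id),
    data = merge(coh$longitudinal, coh$baseline, by = "id"),
    REML = FALSE))
  ref <- lme4::fixef(lme_fit)
  post <- s[grepl("^sbp:", s$parameter), ]
  expect_equal(nrow(post), length(ref))
  dz <- abs(post$mean - ref) / pmax(post$sd, 1e-6)
  expect_true(mean(dz < 3) >= 0.9)
})

test_that("information criteria reduce and scale as expected", {
  coh <- generate_cohort(cohort_config(n_subjects = 30), seed = 13)
  fit <- run_mcmc(coh, mcmc_control(chains = 1, iter = 60, burnin = 30,
                                    thin = 30), seed = 2)
  # single stored draw: DIC collapses to the deviance at that draw
  expect_equal(nrow(fit$pointwise), 1)
  crit1 <- model_fit_criteria(fit)
  expect_equal(crit1$p_waic, 0)
  expect_equal(crit1$p_dic, 0, tolerance = 1e-6)
  expect_equal(crit1$dic, crit1$deviance_at_mean, tolerance = 1e-6)
  fit2 <- run_mcmc(coh, mcmc_control(chains = 2, iter = 400, burnin = 200,
                                     thin = 10), seed = 2)
  crit <- model_fit_criteria(fit2)
  expect_true(is.finite(crit$dic) && is.finite(crit$waic))
  # duplicating every subject's likelihood doubles WAIC (additivity)
  fit_dup <- fit2
  fit_dup$pointwise <- cbind(fit2$pointwise, fit2$pointwise)
  fit_dup$loglik_at_mean <- 2 * fit2$loglik_at_mean
  crit_dup <- model_fit_criteria(fit_dup)
  expect_equal(crit_dup$waic, 2 * crit$waic, tolerance = 1e-10)
  expect_equal(crit_dup$dic, 2 * crit$dic, tolerance = 1e-8)
  nofit <- fit2; nofit$pointwise <- NULL
  expect_error(model_fit_criteria(nofit), "pointwise")
})

test_that("dynamic prediction matches the closed form when unlinked", {
  truth <- joint_params(zero_lmm(Sigma = diag(4)), const_hazard(0.1))
  row <- reference_row()
  hist <- data.frame(time_months = c(0, 1, 2), sbp_mmhg = c(0.3, -0.2, 0.1),
                     dbp_mmhg = c(0.1, 0.4, -0.3))
  pr <- dynamic_prediction(truth, row, hist, t_obs = 2,
                           horizons = c(2, 4, 8, 12), seed = 6)
  expect_equal(pr$mean[1], 1)
  expect_true(all(diff(pr$mean) <= 0))
  expect_equal(pr$mean, exp(-0.1 * (pr$horizon - 2)), tolerance = 1e-8)
  expect_error(dynamic_prediction(truth, row, hist, 5, c(3, 6)),
               "precede")
})

test_that("dynamic prediction from a fitted model gives sane bands", {
  coh <- generate_cohort(cohort_config(n_subjects = 60), seed = 10)
  fit <- run_mcmc(coh, mcmc_control(chains = 1, iter = 400, burnin = 200,
                                    thin = 10), seed = 12)
  id1 <- coh$baseline$id[1]
  hist <- coh$longitudinal[coh$longitudinal$id == id1, ][1:3, ]
  pr <- dynamic_prediction(fit, coh$baseline[1, , drop = FALSE], hist,
                           t_obs = 2, horizons = c(2, 6, 12), ndraws = 40,
                           seed = 3)
  expect_equal(pr$mean[1], 1)
  expect_true(all(diff(pr$mean) <= 0))
  expect_true(all(pr$lower <= pr$mean + 1e-12 &
                    pr$mean <= pr$upper + 1e-12))
})
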