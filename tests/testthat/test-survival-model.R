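test_that("hazard composes baseline, covariates and marker link", {
  lmm0 <- zero_lmm()
  row <- reference_row()
  hp <- const_hazard(0.1)
  expect_equal(hazard(c(0, 3, 100), hp, lmm0, row), rep(0.1, 3))
  expect_error(hazard(-1, hp, lmm0, row), "negative")
  # proportional hazards: switching on a binary covariate with log(2)
  hp2 <- hp; hp2$gamma[] <- log(2)
  male <- transform(row, sex = "Male")
  expect_equal(hazard(5, hp2, lmm0, male), 2 * hazard(5, hp2, lmm0, row))
  # value-of-SBP association: +1 mmHg multiplies the hazard by exp(rho)
  hp3 <- hp; hp3$rho[1] <- -0.1128
  lmm_a <- zero_lmm(); lmm_b <- zero_lmm()
  lmm_b$beta$sbp["(Intercept)"] <- 1
  expect_equal(hazard(2, hp3, lmm_b, row) / hazard(2, hp3, lmm_a, row),
               exp(-0.1128), tolerance = 1e-12)
  expect_equal(round(exp(-0.1128), 4), 0.8933)
})

test_that("piecewise quadrature reproduces closed-form cumulative hazards", {
  lmm0 <- zero_lmm()
  row <- reference_row()
  expect_equal(cumulative_hazard(10, const_hazard(0.1), lmm0, row), 1,
               tolerance = 1e-10)
  hp_pw <- hazard_params(log(c(0.1, 0.2)), c(0, 5),
                         gamma = c(sexMale = 0), rho = numeric(4))
  expect_equal(cumulative_hazard(10, hp_pw, lmm0, row), 1.5,
               tolerance = 1e-10)
  # linear trajectory with value association: exact exponential-ramp form
  a <- 2; bb <- -0.15; rho1 <- -0.3; h0 <- 0.2
  lmm_lin <- zero_lmm()
  lmm_lin$beta$sbp["(Intercept)"] <- a
  lmm_lin$beta$sbp["time"] <- bb
  hp_lin <- const_hazard(h0); hp_lin$rho[1] <- rho1
  for (T in c(1, 7, 25)) {
    closed <- h0 * exp(rho1 * a) * (exp(rho1 * bb * T) - 1) / (rho1 * bb)
    expect_equal(cumulative_hazard(T, hp_lin, lmm_lin, row), closed,
                 tolerance = 1e-8)
  }
})

test_that("cumulative hazard is zero at origin and non-decreasing", {
  set.seed(404)
  row <- reference_row()
  for (rep in 1:10) {
    hp <- hazard_params(rnorm(3, -2, 0.5), c(0, 4, 9),
                        gamma = c(sexMale = rnorm(1, 0, 0.3)),
                        rho = rnorm(4, 0, 0.02))
    lmm <- zero_lmm()
    lmm$beta$sbp["(Intercept)"] <- rnorm(1, 10, 2)
    lmm$beta$sbp["time"] <- rnorm(1, 0, 0.2)
    b <- rnorm(4, 0, 0.5)
    expect_equal(cumulative_hazard(0, hp, lmm, row, b), 0)
    lam <- vapply(seq(0, 20, by = 2.5),
                  function(T) cumulative_hazard(T, hp, lmm, row, b), 0)
    expect_true(all(diff(lam) >= 0))
  }
})

test_that("event log-likelihood matches a dense numerical oracle", {
  lmm0 <- zero_lmm()
  row <- reference_row()
  hp <- const_hazard(0.1)
  expect_equal(loglik_event(7, 0, hp, lmm0, row), -0.7, tolerance = 1e-10)
  expect_equal(loglik_event(10, 1, hp, lmm0, row), log(0.1) - 1,
               tolerance = 1e-10)
  expect_error(loglik_event(-2, 1, hp, lmm0, row), "negative")
  expect_error(loglik_event(2, 2, hp, lmm0, row), "indicator")
  set.seed(8)
  hp_r <- hazard_params(c(-2.2, -1.8), c(0, 6),
                        gamma = c(sexMale = 0.4), rho = c(-0.05, 0.1, 0.02, 0))
  lmm_r <- zero_lmm()
  lmm_r$beta$sbp[] <- c(15, -0.4, 0.1)
  lmm_r$beta$dbp[] <- c(8, -0.2, 0.05)
  row_m <- transform(reference_row(), sex = "Male", age = 3)
  b <- c(1.5, 0.2, -0.8, 0.1)
  T <- 11; ev <- 1
  tt <- seq(0, T, length.out = 10001)
  hh <- hazard(tt, hp_r, lmm_r, row_m, b)
  lam_trap <- sum((hh[-1] + hh[-length(hh)]) / 2 * diff(tt))
  oracle <- ev * log(hazard(T, hp_r, lmm_r, row_m, b)) - lam_trap
  expect_equal(loglik_event(T, ev, hp_r, lmm_r, row_m, b), oracle,
               tolerance = 1e-6)
})

test_that("Kaplan-Meier estimate matches hand product-limit results", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$curve$surv[km2$curve$time == 1], 2 / 3)
  expect_equal(km2$curve$surv[km2$curve$time == 3], 0)
  km3 <- km_estimate(c(4, 6, 9), c(0, 0, 0))
  expect_true(all(km3$curve$surv == 1))
  expect_true(is.na(km3$median))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test agrees with the hypergeometric oracle", {
  t1 <- c(2, 4, 4, 7, 9); e1 <- c(1, 1, 0, 1, 1)
  dup <- logrank_test(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 5))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_error(logrank_test(t1, e1, rep("a", 5)), "two")
  t2 <- c(1, 3, 5, 6, 8); e2 <- c(1, 0, 1, 1, 0)
  res <- logrank_test(c(t1, t2), c(e1, e2), rep(c("a", "b"), each = 5))
  # direct O-E / V computation over distinct event times
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(c(0, 1), each = 5)
  oe <- 0; vv <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at <- times >= tt
    n <- sum(at); n1 <- sum(at & grp == 1)
    d <- sum(events == 1 & times == tt)
    d1 <- sum(events == 1 & times == tt & grp == 1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) vv <- vv + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$statistic, oe^2 / vv, tolerance = 1e-8)
  expect_equal(res$df, 1)
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(2024)
  times <- rexp(200, 0.1)
  events <- rbinom(200, 1, 0.8)
  ps <- replicate(200, {
    logrank_test(times, events, sample(rep(c("a", "b"), each = 100)))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
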