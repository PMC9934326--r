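test_that("build_design uses reference-cell coding with Z = (1, t)", {
  row <- reference_row()
  spec <- design_spec()
  d <- build_design(row, 0, spec)
  expect_equal(unname(d$sbp["(Intercept)"]), 1)
  expect_true(all(d$sbp[-1] == 0))
  expect_true(all(d$dbp[-1] == 0))
  expect_equal(d$Z, c(1, 0))
  row$sex <- "Male"; row$residence <- "Urban"
  d3 <- build_design(row, 3, spec)
  expect_equal(d3$Z, c(1, 3))
  expect_equal(unname(d3$sbp["residenceUrban"]), 1)
  expect_equal(unname(d3$sbp["time"]), 3)
  expect_equal(unname(d3$survival["sexMale"]), 1)
  expect_error(build_design(transform(row, drug = "Aspirin"), 0, spec),
               "unknown category")
  expect_error(build_design(row[, setdiff(names(row), "age")], 0, spec),
               "not found")
})

test_that("urban residence shifts the SBP mean by its fitted coefficient", {
  truth <- default_truth()
  rural <- reference_row(); urban <- transform(rural, residence = "Urban")
  m_r <- marker_mean(truth$lmm, numeric(4), rural, 3)
  m_u <- marker_mean(truth$lmm, numeric(4), urban, 3)
  expect_equal(unname(m_u[1, "sbp"] - m_r[1, "sbp"]), 4.2451)
})

test_that("marker_mean is the exact linear predictor", {
  lmm0 <- zero_lmm()
  row <- reference_row()
  expect_equal(unname(marker_mean(lmm0, numeric(4), row, 5)[1, ]), c(0, 0))
  truth <- default_truth()
  m0 <- marker_mean(truth$lmm, numeric(4), row, 0)
  expect_equal(unname(m0[1, "sbp"]), 96.9114)
  m10 <- marker_mean(truth$lmm, numeric(4), row, 10)
  expect_equal(unname(m10[1, "sbp"]), 96.9114 - 10 * 0.8399)
  # adding k to the intercept shifts the mean by k
  shifted <- truth$lmm
  shifted$beta$sbp["(Intercept)"] <- shifted$beta$sbp["(Intercept)"] + 2.5
  expect_equal(marker_mean(shifted, numeric(4), row, 7)[1, "sbp"],
               marker_mean(truth$lmm, numeric(4), row, 7)[1, "sbp"] + 2.5)
})

test_that("marker_slope is the time coefficient plus the random slope", {
  truth <- default_truth()
  row <- reference_row()
  sl <- marker_slope(truth$lmm, numeric(4), row, c(0, 5, 20))
  expect_equal(unname(sl[, "sbp"]), rep(-0.8399, 3))
  expect_equal(unname(sl[, "dbp"]), rep(-0.6199, 3))
  sl_b <- marker_slope(truth$lmm, c(0, 1, 0, 0), row, 0)
  expect_equal(sl_b[1, "sbp"], sl[1, "sbp"] + 1)
  expect_equal(unname(marker_slope(zero_lmm(), numeric(4), row, 0)[1, ]),
               c(0, 0))
})

test_that("marginal covariance reproduces the evolution of association", {
  lmm <- default_truth()$lmm
  expect_equal(marginal_covariance(lmm, 0)$correlation, 0.260,
               tolerance = 0.001 / 0.260)
  expect_equal(marginal_covariance(lmm, 1)$correlation, 0.2468,
               tolerance = 1e-3)
  # with no random effects the two markers are independent
  expect_equal(marginal_covariance(zero_lmm(), 3)$correlation, 0)
})

test_that("marginal correlation is bounded and variance exceeds noise", {
  set.seed(42)
  for (rep in 1:20) {
    A <- matrix(rnorm(16), 4)
    Sigma <- crossprod(A) + diag(4) * 1e-6
    lmm <- lmm_params(c("(Intercept)" = 0, time = 0, age = 0),
                      c("(Intercept)" = 0, time = 0, age = 0),
                      Sigma, c(2, 3), spec = tiny_spec())
    for (t in c(0, 0.5, 3, 17)) {
      mc <- marginal_covariance(lmm, t)
      expect_gte(1, abs(mc$correlation))
      expect_gte(mc$covariance[1, 1], 4)
      expect_gte(mc$covariance[2, 2], 9)
    }
  }
  # equality with the residual variance iff the random-effect block is zero
  mc0 <- marginal_covariance(zero_lmm(sigma_eps = c(2, 3)), 5)
  expect_equal(mc0$covariance[1, 1], 4)
  expect_equal(mc0$covariance[2, 2], 9)
})

test_that("longitudinal log-likelihood matches a per-point oracle", {
  # one visit observed exactly at its mean with unit noise: each marker
  # contributes the standard-normal log-density at zero
  one <- data.frame(id = 1, time_months = 0, sbp_mmhg = 0, dbp_mmhg = 0)
  expect_equal(loglik_longitudinal(zero_lmm(), matrix(0, 1, 4), one,
                                   reference_row()),
               2 * (-0.5 * log(2 * pi)))
  coh <- tiny_joint_data(n = 5)
  lmm <- coh$truth$lmm
  ll <- loglik_longitudinal(lmm, coh$effects, coh$longitudinal,
                            coh$baseline)
  # brute-force oracle: loop over every record and marker
  oracle <- 0
  for (k in seq_len(nrow(coh$longitudinal))) {
    rec <- coh$longitudinal[k, ]
    i <- match(rec$id, coh$baseline$id)
    m <- marker_mean(lmm, coh$effects[i, ],
                     coh$baseline[i, , drop = FALSE], rec$time_months)
    oracle <- oracle +
      dnorm(rec$sbp_mmhg, m[1, "sbp"], lmm$sigma_eps[["sbp"]], log = TRUE) +
      dnorm(rec$dbp_mmhg, m[1, "dbp"], lmm$sigma_eps[["dbp"]], log = TRUE)
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
  # additive over subjects and invariant to row order
  ids <- unique(coh$longitudinal$id)
  parts <- vapply(ids, function(i) {
    loglik_longitudinal(lmm, coh$effects,
                        coh$longitudinal[coh$longitudinal$id == i, ],
                        coh$baseline)
  }, 0)
  expect_equal(sum(parts), ll, tolerance = 1e-10)
  shuf <- coh$longitudinal[sample(nrow(coh$longitudinal)), ]
  expect_equal(loglik_longitudinal(lmm, coh$effects, shuf, coh$baseline),
               ll, tolerance = 1e-10)
  bad <- lmm; bad$sigma_eps[1] <- 0
  expect_error(loglik_longitudinal(bad, coh$effects, coh$longitudinal,
                                   coh$baseline), "positive")
})
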