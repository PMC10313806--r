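test_that("the Wald ratio divides effects and propagates the outcome SE", {
  r <- wald_ratio(list(gamma = 0.1, se_gamma = 0.01, alpha = 0.02, se_alpha = 0.01))
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1)
  r2 <- wald_ratio(list(gamma = -0.1, se_gamma = 0.01, alpha = 0.02, se_alpha = 0.01))
  expect_equal(r2$beta, -0.2)
  expect_error(wald_ratio(list(gamma = 0, se_gamma = 1, alpha = 1, se_alpha = 1)),
               "gamma")
})

test_that("the second-order Wald SE matches a Monte-Carlo oracle within 2%", {
  inst <- list(gamma = 0.1, se_gamma = 0.005, alpha = 0.03, se_alpha = 0.01)
  r <- wald_ratio(inst, second_order = TRUE)
  set.seed(123)
  draws <- rnorm(1e6, inst$alpha, inst$se_alpha) /
    rnorm(1e6, inst$gamma, inst$se_gamma)
  expect_equal(r$se, sd(draws), tolerance = 0.02)
})

test_that("IVW reproduces a shared ratio exactly with zero heterogeneity", {
  inst <- data.frame(gamma = c(0.1, 0.2, 0.3), se_gamma = 0.01,
                     alpha = c(0.1, 0.2, 0.3) * 0.4, se_alpha = c(0.01, 0.02, 0.03))
  r <- mr_ivw(inst)
  expect_equal(r$beta, 0.4, tolerance = 1e-12)
  expect_equal(r$Q, 0, tolerance = 1e-12)
  expect_equal(cochran_q(inst, 0.4)$pvalue, 1)
})

test_that("IVW equals weighted least squares through the origin", {
  inst <- data.frame(gamma = c(0.10, 0.20, 0.15), se_gamma = 0.01,
                     alpha = c(0.020, 0.050, 0.030), se_alpha = 0.010)
  r <- mr_ivw(inst)
  # equal outcome SEs: the solution is sum(g*a)/sum(g^2) = 0.0165/0.0725
  expect_equal(r$beta, 0.0165 / 0.0725, tolerance = 1e-12)
  expect_equal(r$beta, oracle_wls_origin(inst), tolerance = 1e-10)
  expect_error(mr_ivw(inst[1, , drop = FALSE]), "wald_ratio")

  # fixed and multiplicative random effects share the point estimate;
  # the MRE standard error is never smaller
  set.seed(41)
  for (i in 1:20) {
    ri <- random_instruments(8)
    fx <- mr_ivw(ri, "fixed")
    mre <- mr_ivw(ri, "multiplicative_random_effects")
    expect_equal(fx$beta, mre$beta)
    expect_gte(mre$se, fx$se)
    expect_equal(fx$beta, oracle_wls_origin(ri), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact linear relation and matches the oracle", {
  g <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  inst <- data.frame(gamma = g, se_gamma = 0.01,
                     alpha = 0.013 + 0.37 * g, se_alpha = c(1, 2, 3, 4, 5) / 100)
  r <- mr_egger(inst)
  expect_equal(r$beta, 0.37, tolerance = 1e-10)
  expect_equal(r$intercept, 0.013, tolerance = 1e-10)

  set.seed(17)
  ri <- random_instruments(20)
  r2 <- mr_egger(ri)
  flip <- sign(ri$gamma)
  sol <- unname(oracle_wls_intercept(ri$gamma * flip, ri$alpha * flip,
                                     1 / ri$se_alpha^2))
  expect_equal(r2$intercept, sol[1], tolerance = 1e-10)
  expect_equal(r2$beta, sol[2], tolerance = 1e-10)

  # joint sign flips of any subset leave the canonical fit unchanged
  ri3 <- ri
  pick <- seq(1, 20, by = 3)
  ri3$gamma[pick] <- -ri3$gamma[pick]
  ri3$alpha[pick] <- -ri3$alpha[pick]
  r3 <- mr_egger(ri3)
  expect_equal(r3$beta, r2$beta, tolerance = 1e-12)
  expect_equal(r3$intercept, r2$intercept, tolerance = 1e-12)
  expect_error(mr_egger(ri[1:2, ]), "3")
})

test_that("median estimators interpolate the cumulative weight at one half", {
  inst <- data.frame(gamma = 1, se_gamma = 0.01,
                     alpha = c(0.1, 0.2, 0.9), se_alpha = 0.05)
  r <- median_estimator(inst, "simple", n_boot = 50, seed = 1)
  expect_equal(r$beta, 0.2)

  # one instrument holding the weight majority anchors the estimate
  inst2 <- data.frame(gamma = c(1, 1, 1, 1), se_gamma = 0.01,
                      alpha = c(0.1, 0.3, 0.35, 0.4),
                      se_alpha = c(0.01, 0.5, 0.5, 0.5))
  r2 <- median_estimator(inst2, "inverse_variance", n_boot = 50, seed = 1)
  expect_lt(abs(r2$beta - 0.1), 0.05)

  set.seed(23)
  for (i in 1:10) {
    ri <- random_instruments(5)
    w <- ri$gamma^2 / ri$se_alpha^2
    r3 <- median_estimator(ri, "inverse_variance", n_boot = 10, seed = 2)
    expect_equal(r3$beta, oracle_weighted_median(ri$alpha / ri$gamma, w),
                 tolerance = 1e-12)
  }
  expect_error(median_estimator(inst), "seed")
})

test_that("bootstrap methods are bit-reproducible under a fixed seed", {
  set.seed(3)
  ri <- random_instruments(10)
  a <- median_estimator(ri, "inverse_variance", n_boot = 200, seed = 99)
  b <- median_estimator(ri, "inverse_variance", n_boot = 200, seed = 99)
  expect_identical(a, b)
  p1 <- presso_global(ri, n_sim = 200, seed = 7)
  p2 <- presso_global(ri, n_sim = 200, seed = 7)
  expect_identical(p1, p2)
})

test_that("Cochran's Q sums weighted squared deviations and ignores order", {
  set.seed(19)
  ri <- random_instruments(12)
  b <- mr_ivw(ri)$beta
  h <- cochran_q(ri, b)
  w <- ri$gamma^2 / ri$se_alpha^2
  expect_equal(h$Q, sum(w * (ri$alpha / ri$gamma - b)^2), tolerance = 1e-12)
  expect_equal(h$df, 11)
  perm <- ri[sample.int(12), ]
  expect_equal(cochran_q(perm, b)$Q, h$Q, tolerance = 1e-12)
})

test_that("a planted pleiotropic outlier is flagged as the top outlier", {
  set.seed(6)
  inst <- simulate_instruments(k = 12, true_beta = 0.2)
  inst$alpha[5] <- inst$alpha[5] + 30 * inst$se_alpha[5]
  pr <- presso_global(inst, n_sim = 500, seed = 11)
  expect_lt(pr$global_p, 0.05)
  expect_equal(pr$outliers$variant_id[1], "snp005")  # ranked top outlier
  expect_true(pr$outliers$flagged[1])
  expect_error(presso_global(inst[1:3, ], n_sim = 10, seed = 1), "4")
})

test_that("odds-ratio conversion exponentiates the estimate and bounds", {
  r <- wald_ratio(list(gamma = 1, se_gamma = 0.1, alpha = 0, se_alpha = 0.1))
  expect_equal(r$or_, 1)
  expect_lt(r$or_low, 1)
  expect_gt(r$or_high, 1)
  r2 <- wald_ratio(list(gamma = 1, se_gamma = 0.1, alpha = log(2),
                        se_alpha = 1e-12))
  expect_equal(r2$or_, 2, tolerance = 1e-9)
  # monotone in beta
  betas <- seq(-1, 1, by = 0.25)
  ors <- vapply(betas, function(b) {
    wald_ratio(list(gamma = 1, se_gamma = 0.1, alpha = b, se_alpha = 0.1))$or_
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})
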