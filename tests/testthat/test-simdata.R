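test_that("covariance cases reproduce their printed entries", {
  # Case I: diagonal 0.2, no correlation anywhere
  c1 <- build_covariance("I", p = 6, m = 4, m_p = 0.5)
  expect_equal(c1$matrix, diag(0.2, 6))
  # Case II: exchangeable 0.02 between the two significant genes only
  c2 <- build_covariance("II", p = 4, m = 4, m_p = 0.5)
  expect_equal(c2$sig_indices, 1:2)
  expect_equal(c2$matrix[1, 2], 0.02)
  expect_equal(c2$matrix[1, 3], 0)
  expect_equal(diag(c2$matrix), rep(0.2, 4))
  # Case III: autoregressive decay; significant pair (1, 3)
  c3 <- build_covariance("III", p = 6, m = 6, m_p = 0.5)
  expect_equal(c3$matrix[1, 3], 0.2 * 0.1^2)
  expect_equal(c3$matrix[1, 2], 0.2 * 0.1)
  expect_equal(c3$matrix[1, 4], 0)   # gene 4 is not significant
  # Case IV: symmetric, seeded draws are reproducible
  c4a <- build_covariance("IV", p = 10, m = 10, m_p = 0.8, seed = 5)
  c4b <- build_covariance("IV", p = 10, m = 10, m_p = 0.8, seed = 5)
  expect_identical(c4a$matrix, c4b$matrix)
  expect_equal(c4a$matrix, t(c4a$matrix))
  expect_gte(min(eigen(c4a$matrix, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("an indefinite unstructured draw is repaired, never returned as-is", {
  # large significant block at this correlation scale is frequently indefinite
  found_repair <- FALSE
  for (s in 1:20) {
    cv <- suppressMessages(
      build_covariance("IV", p = 120, m = 120, m_p = 1, seed = s))
    ev <- eigen(cv$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    if (cv$repaired) found_repair <- TRUE
  }
  expect_true(found_repair)
})

test_that("coefficient draws respect count, support and centering", {
  co <- draw_coefficients("A", p = 200, m = 50, m_p = 0.3, seed = 2)
  expect_equal(sum(co$beta != 0), 15)    # floor(50 * 0.3)
  expect_true(all(co$beta[1:15] > 0.2 & co$beta[1:15] < 0.6))
  expect_true(all(co$beta[16:200] == 0))
  expect_error(draw_coefficients("A", p = 10, m = 4, m_p = 0.1),
               "no significant genes")
  # Case B is centered: Monte-Carlo mean within 3 * 0.5 / sqrt(N)
  cb <- draw_coefficients("B", p = 4000, m = 4000, m_p = 1, seed = 3)
  expect_lt(abs(mean(cb$beta)), 3 * 0.5 / sqrt(4000))
})

test_that("expression draws are reproducible and match the target covariance", {
  cv <- build_covariance("I", p = 5)
  X1 <- simulate_expression(100, cv, seed = 9)
  X2 <- simulate_expression(100, cv, seed = 9)
  expect_identical(X1, X2)
  expect_equal(dim(simulate_expression(1, cv, seed = 1)), c(1L, 5L))
  Xbig <- simulate_expression(20000, cv, seed = 10)
  emp <- crossprod(Xbig) / 20000
  expect_lt(max(abs(emp - diag(0.2, 5))), 0.01)
  # correlated case: empirical covariance tracks the realized matrix
  cv2 <- build_covariance("II", p = 6, m = 6, m_p = 1)
  X3 <- simulate_expression(20000, cv2, seed = 11)
  expect_lt(max(abs(crossprod(X3) / 20000 - cv2$matrix)), 0.01)
})

test_that("censoring calibration has the exact closed form under the null", {
  cv <- build_covariance("I", p = 10)
  beta0 <- numeric(10)
  expect_equal(calibrate_censoring_rate(0.5, cv, beta0), 0.005)
  expect_equal(calibrate_censoring_rate(0.3, cv, beta0),
               0.005 * 0.3 / 0.7, tolerance = 1e-12)
  expect_equal(calibrate_censoring_rate(0, cv, beta0), 0)
  expect_error(calibrate_censoring_rate(1, cv, beta0), "below 1")
})

test_that("root-found censoring rates hit the target fraction in round-trip simulation", {
  cv <- build_covariance("II", p = 50, m = 50, m_p = 0.5)
  beta <- draw_coefficients("A", p = 50, m = 50, m_p = 0.5, seed = 21)$beta
  lam <- calibrate_censoring_rate(0.3, cv, beta, mc_size = 20000, seed = 22)
  set.seed(23)
  cens <- vapply(1:50, function(i) {
    X <- simulate_expression(80, cv)
    sv <- simulate_survival(X, beta, lambda_cens = lam)
    mean(sv$status == 0)
  }, numeric(1))
  expect_lt(abs(mean(cens) - 0.3), 0.03)
})

test_that("survival generation follows the Cox inverse transform", {
  cv <- build_covariance("I", p = 2)
  X <- simulate_expression(20000, cv, seed = 31)
  sv <- simulate_survival(X, c(0, 0), baseline_rate = 0.005,
                          lambda_cens = 0, seed = 32)
  expect_true(all(sv$status == 1))
  # null times are Exponential(0.005): mean 200 within 3 standard errors
  expect_lt(abs(mean(sv$time) - 200), 3 * 200 / sqrt(20000))
  # doubling the hazard halves the times for identical uniform draws
  n <- 50
  Xs <- matrix(1, n, 1)
  t1 <- simulate_survival(Xs, 0.3, lambda_cens = 0, seed = 33)$time
  t2 <- simulate_survival(Xs, 0.3 + log(2), lambda_cens = 0, seed = 33)$time
  expect_equal(t1 / 2, t2, tolerance = 1e-12)
})

test_that("single-gene simulation recovers the generating coefficient", {
  cfg <- sim_config(p = 1, n = 500, m = 1, m_p = 1, c_p = 0,
                    cov_case = "I", coef_case = "A")
  cov <- build_covariance("I", 1)
  set.seed(41)
  beta_true <- 0.4
  X <- simulate_expression(500, cov)
  sv <- simulate_survival(X, beta_true, lambda_cens = 0)
  fit <- fit_univariate_cox(X[, 1], sv)
  expect_lt(abs(fit$b - beta_true), 3 * fit$se)
})

test_that("whole datasets are reproducible byte-for-byte from the seed", {
  cfg <- sim_config(p = 30, n = 40, m = 10, m_p = 0.5, c_p = 0.3,
                    cov_case = "III", coef_case = "B")
  d1 <- simulate_dataset(cfg, seed = 77)
  d2 <- simulate_dataset(cfg, seed = 77)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$surv$time, d2$surv$time)
  expect_identical(d1$beta_true, d2$beta_true)
  d3 <- simulate_dataset(cfg, seed = 78)
  expect_false(identical(d1$X, d3$X))
  # coefficient vector is redrawn per replication seed
  expect_false(identical(d1$beta_true, d3$beta_true))
  expect_equal(sum(d1$beta_true != 0), 5)
})
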