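# Brute-force two-sample KS-type running statistic: difference of the
# member / non-member empirical CDFs over rank positions, signed value of
# maximal magnitude. Independent of the package's cumulative-sum path.
ks_oracle <- function(member) {
  p <- length(member)
  m <- sum(member)
  d <- vapply(seq_len(p), function(j) {
    sum(member[seq_len(j)]) / m - sum(!member[seq_len(j)]) / (p - m)
  }, numeric(1))
  d[which.max(abs(d))]
}

test_that("rank_genes orders by absolute value with stable ties", {
  r <- rank_genes(c(0.5, -3, 2), c("g1", "g2", "g3"))
  expect_equal(r$gene_ids, c("g2", "g3", "g1"))
  expect_equal(r$scores, c(3, 2, 0.5))
  expect_equal(r$signed_scores, c(-3, 2, 0.5))
  r0 <- rank_genes(c(0, 0, 0), c("a", "b", "c"))
  expect_equal(r0$gene_ids, c("a", "b", "c"))
  expect_error(rank_genes(c(1, NaN), c("a", "b")), "finite")
  expect_error(rank_genes(c(1, 2), c("a", "a")), "duplicate")
})

test_that("enrichment score reproduces hand-computed running sums", {
  r <- rank_genes(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  top <- enrichment_score(r, c("a", "b"), w = 0)
  expect_equal(top$details$path, c(0.5, 1, 0.5, 0))
  expect_equal(top$statistic, 1)
  bottom <- enrichment_score(r, c("c", "d"), w = 0)
  expect_equal(bottom$statistic, -1)
  # members a (weight 4/6) and c (weight 2/6); decrements 1/2
  weighted <- enrichment_score(r, c("a", "c"), w = 1)
  expect_equal(weighted$details$path, c(2 / 3, 1 / 6, 1 / 2, 0),
               tolerance = 1e-12)
  expect_equal(weighted$statistic, 2 / 3, tolerance = 1e-12)
  expect_error(enrichment_score(r, c("zz"), w = 0), "not represented")
  expect_error(enrichment_score(r, c("a", "b", "c", "d"), w = 0),
               "decrement")
})

test_that("the running sum terminates at zero for random placements and both weights", {
  set.seed(501)
  for (i in 1:500) {
    p <- sample(10:80, 1)
    m <- sample(1:(p - 1), 1)
    z <- rnorm(p)
    r <- rank_genes(z)
    members <- sample(r$gene_ids, m)
    for (w in 0:1) {
      es <- enrichment_score(r, members, w = w)
      expect_lt(abs(es$details$path[p]), 1e-10)
      if (w == 0) expect_true(abs(es$statistic) <= 1 + 1e-12)
    }
  }
})

test_that("the unweighted score equals the brute-force KS running statistic", {
  set.seed(502)
  for (i in 1:100) {
    p <- sample(8:60, 1)
    m <- sample(1:(p - 1), 1)
    r <- rank_genes(rnorm(p))
    members <- sample(r$gene_ids, m)
    es <- enrichment_score(r, members, w = 0)
    expect_equal(es$statistic, ks_oracle(r$gene_ids %in% members),
                 tolerance = 1e-12)
  }
})

test_that("Global Test statistic matches brute-force matrix arithmetic", {
  sv <- survival_data(c(1, 2, 3), c(1, 1, 1))
  X <- matrix(c(1, -2, 3, 0, 2, -1), nrow = 3)
  gt <- global_test_stat(X, sv)
  # independent elementwise evaluation of (d-u)' X X' (d-u) - sum_i (XX')_ii u_i
  u <- c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1)
  r <- c(1, 1, 1) - u
  R <- X %*% t(X)
  T_ref <- 0
  for (i in 1:3) for (j in 1:3) T_ref <- T_ref + r[i] * R[i, j] * r[j]
  for (i in 1:3) T_ref <- T_ref - R[i, i] * u[i]
  expect_equal(gt$statistic, T_ref, tolerance = 1e-8)
  # degree-2 homogeneity and the zero-matrix case
  expect_equal(global_test_stat(2 * X, sv)$statistic, 4 * gt$statistic,
               tolerance = 1e-8)
  expect_equal(global_test_stat(matrix(0, 3, 2), sv)$statistic, 0)
})

test_that("Global Test is invariant to gene order and joint sample reordering", {
  set.seed(503)
  sv <- random_surv(20)
  X <- matrix(rnorm(20 * 6), 20)
  t0 <- global_test_stat(X, sv)$statistic
  expect_equal(global_test_stat(X[, sample(6)], sv)$statistic, t0,
               tolerance = 1e-10)
  perm <- sample(20)
  svp <- survival_data(sv$time[perm], sv$status[perm])
  expect_equal(global_test_stat(X[perm, ], svp)$statistic, t0,
               tolerance = 1e-10)
})

test_that("Wald-type statistic is the sum of squared ratios", {
  expect_equal(wald_type_stat(c(1, -2, 3))$statistic, 14)
  expect_equal(wald_type_stat(c(0, 0))$statistic, 0)
  expect_equal(wald_type_stat(1.7)$statistic, 1.7^2)
  expect_error(wald_type_stat(numeric(0)), "empty")
})

test_that("boosting is inert on an all-zero matrix and linear in the step size", {
  sv <- survival_data(c(2, 3, 5, 7, 11), c(1, 0, 1, 1, 0))
  z5 <- matrix(0, 5, 3)
  fit0 <- boost_cox(z5, sv, boost_control(n_steps = 10))
  expect_equal(fit0$eta, rep(0, 5))
  expect_equal(fit0$coef, rep(0, 3))
  expect_equal(fit0$loglik_path, rep(fit0$loglik0, 10))
  expect_equal(gbst_stat(fit0, sv)$statistic, 0)
  # single update is proportional to the shrinkage factor
  set.seed(504)
  X <- matrix(rnorm(5 * 3), 5)
  f1 <- boost_cox(X, sv, boost_control(n_steps = 1, step_size = 0.1))
  f2 <- boost_cox(X, sv, boost_control(n_steps = 1, step_size = 0.05))
  expect_equal(f1$eta, 2 * f2$eta, tolerance = 1e-10)
})

test_that("boosting selects the column with the largest RSS reduction", {
  set.seed(505)
  n <- 60
  x_sig <- rnorm(n)
  sv <- survival_data(rexp(n, 0.05 * exp(1.5 * x_sig)),
                      rep(1, n))
  X <- cbind(x_sig, matrix(rnorm(n * 5), n))
  fit <- boost_cox(X, sv, boost_control(n_steps = 1))
  # brute-force comparison of the per-column least-squares residual sums
  u <- breslow_cumhaz(sv)$cumhaz_at_sample
  g <- sv$status - u        # gradient of the partial loglik at eta = 0
  rss <- apply(X, 2, function(x) {
    b <- sum(x * g) / sum(x^2)
    sum((g - b * x)^2)
  })
  expect_equal(fit$selected[1], unname(which.min(rss)))
  expect_equal(fit$selected[1], 1L)
})

test_that("eta decomposes as offset plus X coef and the objective never decreases", {
  set.seed(506)
  n <- 40
  X <- matrix(rnorm(n * 8), n)
  sv <- random_surv(n)
  fit <- boost_cox(X, sv, boost_control(n_steps = 50))
  expect_equal(fit$eta, drop(X %*% fit$coef), tolerance = 1e-10)
  expect_true(all(diff(c(fit$loglik0, fit$loglik_path)) >= -1e-8))
  expect_gte(gbst_stat(fit, sv)$statistic, -1e-8)
})

test_that("the boosted statistic is positive on prognostic expression and matches direct evaluation", {
  set.seed(507)
  n <- 60
  x_sig <- rnorm(n)
  sv <- survival_data(rexp(n, 0.05 * exp(1.2 * x_sig)), rep(1, n))
  X <- cbind(x_sig, matrix(rnorm(n * 4), n))
  fit <- boost_cox(X, sv)
  st <- gbst_stat(fit, sv)$statistic
  expect_gt(st, 0)
  expect_equal(st, partial_loglik(fit$eta, sv) - partial_loglik(rep(0, n), sv),
               tolerance = 1e-10)
  expect_equal(fit$loglik_path[fit$control$n_steps] - fit$loglik0, st,
               tolerance = 1e-10)
})

test_that("all five statistics are invariant under joint sample reordering", {
  set.seed(508)
  n <- 30
  p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  sv <- random_surv(n)
  set_idx <- 1:6
  stats_of <- function(X, sv) {
    scan <- cox_wald_scan(X, sv, quiet = TRUE)
    r <- rank_genes(scan$z, colnames(X))
    c(gsea1 = enrichment_score(r, colnames(X)[set_idx], 0)$statistic,
      gsea2 = enrichment_score(r, colnames(X)[set_idx], 1)$statistic,
      gt = global_test_stat(X[, set_idx], sv)$statistic,
      wt = wald_type_stat(scan$z[set_idx])$statistic,
      gbst = gbst_stat(boost_cox(X[, set_idx], sv), sv)$statistic)
  }
  base <- stats_of(X, sv)
  perm <- sample(n)
  svp <- survival_data(sv$time[perm], sv$status[perm])
  expect_equal(stats_of(X[perm, ], svp), base, tolerance = 1e-8)
})
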