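#' Gene-expression covariance structures for the simulator
#'
#' Realizes the p x p covariance matrix of the multivariate-normal
#' expression model. All cases share marginal variance 0.2; off-diagonal
#' entries exist only between pairs of "significant" genes (by convention
#' the first `floor(m * m_p)` genes, the ones later given nonzero survival
#' coefficients):
#'
#' * Case I  — all genes independent: `Sigma = 0.2 * I`.
#' * Case II — exchangeable correlation among significant genes:
#'   `sigma_ij = 0.02`.
#' * Case III — autoregressive decay: `sigma_ij = 0.2 * 0.1^|i - j|`.
#' * Case IV — unstructured: `sigma_ij = 0.2 * rho_ij` with
#'   `rho_ij ~ N(0, 0.1^2)` drawn once per realization (seeded).
#'
#' A Case IV draw can be indefinite for a large significant block; the
#' matrix is then repaired by clipping eigenvalues at 1e-8 and
#' re-symmetrizing, and the repair is reported via a message (never
#' silent).
#'
#' @param case One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param p Total number of genes.
#' @param m Gene-set size.
#' @param m_p Proportion of significant genes in the set.
#' @param seed Seed for the Case IV correlation draws.
#' @return A `covariance_spec` with the realized `matrix`, its upper
#'   Cholesky-type `factor` (`t(factor) %*% factor == matrix`),
#'   `sig_indices`, and a `repaired` flag.
#' @export
build_covariance <- function(case = c("I", "II", "III", "IV"), p, m = 0,
                             m_p = 0, seed = NULL) {
  case <- match.arg(case)
  stopifnot(p >= 1, m <= p, m_p >= 0, m_p <= 1)
  k <- floor(m * m_p)
  sig <- if (k >= 1) seq_len(k) else integer(0)
  Sigma <- diag(0.2, p)
  if (case != "I" && k >= 2) {
    blk <- switch(case,
      II = matrix(0.02, k, k),
      III = 0.2 * 0.1^abs(outer(sig, sig, "-")),
      IV = {
        draw <- function() {
          rho <- matrix(0, k, k)
          rho[upper.tri(rho)] <- rnorm(k * (k - 1) / 2, 0, 0.1)
          0.2 * (rho + t(rho))
        }
        if (is.null(seed)) draw() else with_seed(seed, draw())
      })
    diag(blk) <- 0.2
    Sigma[sig, sig] <- blk
  }
  repaired <- FALSE
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)          # eigenvalue clipping repair
    Sigma <- ev$vectors %*% (vals * t(ev$vectors))
    Sigma <- (Sigma + t(Sigma)) / 2
    repaired <- TRUE
    message(sprintf(
      "covariance Case %s repaired to positive semidefinite (min eigenvalue clipped at 1e-8)",
      case))
    ev <- eigen(Sigma, symmetric = TRUE)
  }
  factor <- sqrt(pmax(ev$values, 0)) * t(ev$vectors)
  structure(list(case = case, p = as.integer(p), sig_indices = sig,
                 sigma_diag = 0.2, matrix = Sigma, factor = factor,
                 repaired = repaired),
            class = "covariance_spec")
}

#' Gene-survival association coefficients for the simulator
#'
#' Draws the Cox regression coefficient vector: the first `floor(m * m_p)`
#' genes (the significant genes) receive nonzero coefficients, the rest are
#' zero.
#'
#' * Case A — positive association: `beta_j ~ U(0.2, 0.6)`.
#' * Case B — random-direction association: `beta_j ~ N(0, 0.5^2)`.
#'
#' @param case `"A"` or `"B"`.
#' @inheritParams build_covariance
#' @param seed Seed for the coefficient draws.
#' @return A `coefficient_spec` with the length-p `beta` vector.
#' @export
draw_coefficients <- function(case = c("A", "B"), p, m, m_p, seed = NULL) {
  case <- match.arg(case)
  stopifnot(p >= 1, m <= p, m_p > 0, m_p <= 1)
  k <- floor(m * m_p)
  if (k == 0) stop("no significant genes requested: floor(m * m_p) == 0")
  draw <- function() {
    if (case == "A") runif(k, 0.2, 0.6) else rnorm(k, 0, 0.5)
  }
  vals <- if (is.null(seed)) draw() else with_seed(seed, draw())
  beta <- numeric(p)
  beta[seq_len(k)] <- vals
  structure(list(case = case, m = as.integer(m), m_p = m_p, beta = beta,
                 n_significant = k),
            class = "coefficient_spec")
}

#' Draw correlated multivariate-normal expression
#'
#' `n` independent samples from `MVN(0, Sigma)` using the factorization
#' stored in the covariance spec.
#'
#' @param n Number of samples (rows).
#' @param cov A [build_covariance] result.
#' @param seed Seed for the Gaussian draws.
#' @return An `n x p` matrix with columns `g1..gp` and rows `s1..sn`.
#' @export
simulate_expression <- function(n, cov, seed = NULL) {
  stopifnot(inherits(cov, "covariance_spec"), n >= 1)
  draw <- function() matrix(rnorm(n * cov$p), n, cov$p)
  Z <- if (is.null(seed)) draw() else with_seed(seed, draw())
  X <- Z %*% cov$factor
  dimnames(X) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(cov$p)))
  X
}

#' Calibrate the exponential censoring rate to a target fraction
#'
#' With event hazard `h(X) = baseline_rate * exp(beta' X)` constant in time
#' and censoring `C ~ Exp(lambda)`, a subject is censored with probability
#' `lambda / (lambda + h(X))` (competing exponentials). The rate solving
#' `E_X[lambda / (lambda + h(X))] = c_p` is found in closed form when
#' `beta == 0` (`lambda = baseline_rate * c_p / (1 - c_p)`) and otherwise
#' by root-finding over a Monte-Carlo approximation of the expectation on
#' fresh expression draws.
#'
#' @param c_p Target censoring fraction in [0, 1).
#' @param cov A [build_covariance] result.
#' @param beta Coefficient vector (length p), e.g. from
#'   [draw_coefficients].
#' @param baseline_rate Constant baseline hazard.
#' @param mc_size Monte-Carlo sample size for the expectation.
#' @param seed Seed for the Monte-Carlo draws.
#' @return The censoring rate `lambda` (0 when `c_p == 0`).
#' @export
calibrate_censoring_rate <- function(c_p, cov, beta,
                                     baseline_rate = 0.005,
                                     mc_size = 10000L, seed = NULL) {
  stopifnot(c_p >= 0)
  if (c_p >= 1) stop("censoring fraction must be below 1")
  if (c_p == 0) return(0)
  nz <- which(beta != 0)
  if (length(nz) == 0) return(baseline_rate * c_p / (1 - c_p))
  sub <- cov$matrix[nz, nz, drop = FALSE]
  evs <- eigen(sub, symmetric = TRUE)
  fac <- sqrt(pmax(evs$values, 0)) * t(evs$vectors)
  draw <- function() matrix(rnorm(mc_size * length(nz)), mc_size)
  Z <- if (is.null(seed)) draw() else with_seed(seed, draw())
  eta <- drop((Z %*% fac) %*% beta[nz])
  h <- baseline_rate * exp(eta)
  f <- function(lam) mean(lam / (lam + h)) - c_p
  upper <- baseline_rate * c_p / (1 - c_p)
  while (f(upper) < 0) upper <- upper * 10
  uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Simulate Cox-model survival with exponential censoring
#'
#' Event times follow a Cox model with constant baseline hazard:
#' `T_i = -log(U_i) / (baseline_rate * exp(beta' X_i))` with
#' `U_i ~ Uniform(0, 1)` (inverse transform). Censoring times are
#' `C_i ~ Exp(lambda_cens)` (none when `lambda_cens == 0`); the observed
#' time is `min(T, C)` and `status = 1` when the event comes first.
#'
#' @param X Expression matrix, samples in rows.
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param baseline_rate Constant baseline hazard.
#' @param lambda_cens Censoring rate from [calibrate_censoring_rate].
#' @param seed Seed for the uniform and censoring draws.
#' @return A [survival_data] object.
#' @export
simulate_survival <- function(X, beta, baseline_rate = 0.005,
                              lambda_cens = 0, seed = NULL) {
  stopifnot(is.matrix(X), length(beta) == ncol(X), lambda_cens >= 0)
  n <- nrow(X)
  h <- baseline_rate * exp(drop(X %*% beta))
  draw <- function() {
    tt <- -log(runif(n)) / h
    cc <- if (lambda_cens > 0) rexp(n, rate = lambda_cens) else rep(Inf, n)
    list(time = pmin(tt, cc), status = as.integer(tt <= cc))
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  survival_data(d$time, d$status, sample_ids = rownames(X))
}

#' Simulation scenario configuration
#'
#' The full generative specification of one scenario: gene universe size,
#' sample size, gene-set size, proportion of significant genes, censoring
#' fraction, covariance and coefficient regimes, and the baseline hazard.
#'
#' @param p Total genes.
#' @param n Samples.
#' @param m Gene-set size (the tested set is genes `1..m`).
#' @param m_p Proportion of significant genes within the set (ignored for
#'   `coef_case = "null"`).
#' @param c_p Censoring fraction in [0, 1).
#' @param cov_case Covariance Case `"I".."IV"`.
#' @param coef_case `"A"`, `"B"`, or `"null"` (all coefficients zero — the
#'   size / type-I-error regime).
#' @param baseline_rate Constant baseline hazard (default 0.005).
#' @return A `sim_config` list.
#' @export
sim_config <- function(p = 200L, n = 80L, m = 50L, m_p = 0.5, c_p = 0,
                       cov_case = "I", coef_case = "A",
                       baseline_rate = 0.005) {
  cov_case <- match.arg(cov_case, c("I", "II", "III", "IV"))
  coef_case <- match.arg(coef_case, c("A", "B", "null"))
  stopifnot(p >= 1, n >= 2, m >= 1, m <= p, m_p >= 0, m_p <= 1,
            c_p >= 0, c_p < 1, baseline_rate > 0)
  if (coef_case != "null" && floor(m * m_p) < 1) {
    stop("power scenario needs floor(m * m_p) >= 1 significant genes")
  }
  structure(list(p = as.integer(p), n = as.integer(n), m = as.integer(m),
                 m_p = m_p, c_p = c_p, cov_case = cov_case,
                 coef_case = coef_case, baseline_rate = baseline_rate),
            class = "sim_config")
}

#' Simulate one full dataset under a scenario
#'
#' One replication of the generative model: (optionally reuse a realized
#' covariance), draw the coefficient vector, calibrate the censoring rate
#' to the target fraction, draw expression, and construct censored survival
#' times. The coefficient vector is redrawn per replication; the covariance
#' realization is fixed per scenario unless rebuilt by the caller.
#'
#' @param config A [sim_config].
#' @param seed Integer master seed for this replication (spawns independent
#'   child seeds for coefficients, calibration, expression and survival).
#' @param cov Optional pre-realized [build_covariance] spec (built from a
#'   child seed otherwise).
#' @param mc_size Monte-Carlo size for censoring calibration.
#' @return A `sim_dataset` with `X` (n x p), `surv`, `beta_true`,
#'   `lambda_cens`, `set_idx` (`1:m`) and the `config`.
#' @export
simulate_dataset <- function(config, seed = 1L, cov = NULL,
                             mc_size = 10000L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- spawn_seeds(seed, 5L)
  if (is.null(cov)) {
    cov <- build_covariance(config$cov_case, config$p, config$m,
                            if (config$coef_case == "null") 0 else config$m_p,
                            seed = seeds[1])
  }
  if (config$coef_case == "null") {
    beta <- numeric(config$p)
  } else {
    beta <- draw_coefficients(config$coef_case, config$p, config$m,
                              config$m_p, seed = seeds[2])$beta
  }
  lambda <- calibrate_censoring_rate(config$c_p, cov, beta,
                                     config$baseline_rate,
                                     mc_size = mc_size, seed = seeds[5])
  X <- simulate_expression(config$n, cov, seed = seeds[3])
  surv <- simulate_survival(X, beta, config$baseline_rate, lambda,
                            seed = seeds[4])
  structure(list(X = X, surv = surv, beta_true = beta,
                 lambda_cens = lambda, set_idx = seq_len(config$m),
                 config = config),
            class = "sim_dataset")
}
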