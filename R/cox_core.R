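#' Construct a survival phenotype object
#'
#' Bundles per-sample follow-up time and event status, the phenotype that
#' every gene-set test conditions on. Times must be positive and at least one
#' event must be observed, otherwise the Cox partial likelihood is
#' degenerate.
#'
#' @param time Positive follow-up times, one per sample (any consistent unit).
#' @param status Event indicator per sample: 1 = event observed, 0 = censored.
#' @param sample_ids Optional unique sample identifiers aligned with `time`.
#'
#' @return An object of class `survival_data` with fields `time`, `status`
#'   and `sample_ids`.
#' @examples
#' survival_data(time = c(5, 8, 12), status = c(1, 0, 1))
#' @export
survival_data <- function(time, status, sample_ids = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != length(status)) {
    stop("time and status must have equal length")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all follow-up times must be positive and finite")
  }
  if (!all(status %in% c(0, 1))) {
    stop("status must be 0 (censored) or 1 (event)")
  }
  if (sum(status) < 1) {
    stop("no events: at least one status == 1 is required")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("s", seq_along(time))
  } else {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != length(time)) {
      stop("sample_ids length must match time")
    }
    if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  }
  structure(list(time = time, status = as.integer(status),
                 sample_ids = sample_ids),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("survival_data: %d samples, %d events (%.1f%% censored)\n",
              length(x$time), sum(x$status),
              100 * mean(x$status == 0)))
  invisible(x)
}

#' @export
length.survival_data <- function(x) length(x$time)

# Sorted-order bookkeeping shared by every partial-likelihood kernel:
# samples ordered by increasing time, with group_start[i] the 0-based index
# of the first sample tied with i (Breslow risk sets).
surv_order <- function(surv) {
  ord <- order(surv$time)
  t_s <- surv$time[ord]
  gs <- integer(length(t_s))
  first <- 1L
  for (i in seq_along(t_s)) {
    if (t_s[i] > t_s[first]) first <- i
    gs[i] <- first - 1L
  }
  list(ord = ord, time = t_s, status = surv$status[ord], group_start = gs)
}

new_cox_fit <- function(row) {
  structure(list(b = row[1], se = row[2], z = row[3],
                 converged = row[4] == 1, n_iter = as.integer(row[5]),
                 degenerate = row[6] == 1),
            class = "cox_fit")
}

#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximizer of the univariate Cox partial likelihood with
#' Breslow tie handling and an observed-information standard error.
#' Step-halving protects against overshooting and a cap on `|b|` flags
#' diverging fits (e.g. a covariate that perfectly separates the events)
#' as non-converged instead of looping.
#'
#' @param x Numeric covariate vector, one value per sample.
#' @param surv A [survival_data] object.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the absolute score.
#' @param b_cap Divergence guard: fits with `|b|` beyond this are flagged
#'   non-converged.
#'
#' @return A `cox_fit` with fields `b` (log-hazard ratio), `se`, `z = b/se`,
#'   `converged`, `n_iter` and `degenerate`.
#' @examples
#' sv <- survival_data(c(2, 4, 6, 8, 10, 12), c(1, 1, 0, 1, 0, 1))
#' fit_univariate_cox(c(0.5, -0.2, 1.1, 0.3, -0.7, 0.9), sv)
#' @export
fit_univariate_cox <- function(x, surv, max_iter = 25L, tol = 1e-8,
                               b_cap = 50) {
  stopifnot(inherits(surv, "survival_data"))
  x <- as.numeric(x)
  if (length(x) != length(surv$time)) {
    stop("covariate length must match the number of samples")
  }
  if (any(!is.finite(x))) stop("covariate contains non-finite values")
  if (max(x) - min(x) <= 1e-12) stop("degenerate covariate")
  so <- surv_order(surv)
  res <- cpp_cox_scan(matrix(x[so$ord], ncol = 1), so$status,
                      so$group_start, as.integer(max_iter), tol, b_cap,
                      FALSE)
  new_cox_fit(res[1, ])
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: b = %.6g, se = %.6g, z = %.6g (%s, %d iterations)\n",
              x$b, x$se, x$z,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Univariate Cox Wald ratio
#'
#' The standardized log-hazard ratio `b/se` for one gene. Degenerate or
#' non-converged fits return 0 with a warning rather than an error, so that
#' genome-wide ranking scans survive constant or pathological genes.
#'
#' @inheritParams fit_univariate_cox
#' @return The Wald ratio (scalar).
#' @export
wald_z <- function(x, surv, max_iter = 25L, tol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) == length(surv$time) && max(x) - min(x) <= 1e-12) {
    warning("degenerate covariate: Wald ratio set to 0")
    return(0)
  }
  fit <- fit_univariate_cox(x, surv, max_iter = max_iter, tol = tol)
  if (!fit$converged || !is.finite(fit$z)) {
    warning("non-converged Cox fit: Wald ratio set to 0")
    return(0)
  }
  fit$z
}

#' Genome-wide univariate Cox Wald scan
#'
#' Fits a univariate Cox model to every gene (column of `X`) and returns the
#' per-gene log-hazard ratio, standard error and Wald ratio. Degenerate and
#' non-converged genes get a Wald ratio of 0; one summary warning is emitted
#' unless `quiet = TRUE`.
#'
#' @param X Numeric matrix, samples in rows, genes in columns.
#' @param surv A [survival_data] object.
#' @param fast_scan If `TRUE`, replace the full Newton fit with the score
#'   statistic at `b = 0` (one evaluation per gene): `z = U(0)/sqrt(I(0))`
#'   and the one-step estimate `b = U/I`. A cheap, permutation-valid
#'   approximation for large scans.
#' @param quiet Suppress the summary warning about degenerate genes.
#' @inheritParams fit_univariate_cox
#'
#' @return A data.frame with columns `b`, `se`, `z`, `converged`,
#'   `degenerate`, one row per gene (named by `colnames(X)`).
#' @export
cox_wald_scan <- function(X, surv, fast_scan = FALSE, max_iter = 25L,
                          tol = 1e-8, b_cap = 50, quiet = FALSE) {
  stopifnot(inherits(surv, "survival_data"), is.matrix(X))
  if (nrow(X) != length(surv$time)) {
    stop("X must have one row per sample")
  }
  so <- surv_order(surv)
  res <- cpp_cox_scan(X[so$ord, , drop = FALSE], so$status, so$group_start,
                      as.integer(max_iter), tol, b_cap, isTRUE(fast_scan))
  bad <- res[, 6] == 1 | res[, 3] == 0
  z <- res[, 3]
  z[res[, 6] == 1] <- 0
  if (!isTRUE(fast_scan)) z[res[, 4] == 0] <- 0
  n_zeroed <- sum(z == 0 & (res[, 6] == 1 | res[, 4] == 0))
  if (!quiet && n_zeroed > 0) {
    warning(sprintf("%d gene(s) degenerate or non-converged; Wald ratio set to 0",
                    n_zeroed))
  }
  data.frame(b = res[, 1], se = res[, 2], z = z,
             converged = res[, 4] == 1, degenerate = res[, 6] == 1,
             row.names = colnames(X))
}

#' Null-model Breslow cumulative hazard
#'
#' The no-covariate Breslow estimator: at each event time the hazard
#' increment is (number of events there) / (number at risk); the cumulative
#' hazard for sample i sums the increments at event times up to its own
#' follow-up time. Its martingale residuals `status - cumhaz` sum to zero.
#'
#' @param surv A [survival_data] object.
#' @return A `baseline_hazard` with `cumhaz_at_sample` (in the original
#'   sample order), `event_times` and `increments`.
#' @examples
#' breslow_cumhaz(survival_data(c(1, 2, 3), c(1, 1, 1)))
#' @export
breslow_cumhaz <- function(surv) {
  stopifnot(inherits(surv, "survival_data"))
  so <- surv_order(surv)
  ev <- which(so$status == 1)
  ev_times <- unique(so$time[ev])
  inc <- vapply(ev_times, function(tt) {
    sum(so$time[ev] == tt) / sum(so$time >= tt)
  }, numeric(1))
  cum <- cumsum(inc)
  # cumulative hazard at each sample's own time
  idx <- findInterval(so$time, ev_times)
  u_sorted <- c(0, cum)[idx + 1]
  u <- numeric(length(u_sorted))
  u[so$ord] <- u_sorted
  structure(list(cumhaz_at_sample = u, event_times = ev_times,
                 increments = inc),
            class = "baseline_hazard")
}

#' Cox partial log-likelihood of a linear predictor
#'
#' Evaluates `l(eta) = sum over events i of eta_i - log(sum over the risk set
#' of exp(eta_j))` with Breslow risk sets (`t_j >= t_i`) and a max-shift
#' inside the log-sum-exp for numerical stability. Invariant to adding a
#' constant to `eta`, which is why the boosting offset can be all zeros.
#'
#' @param eta Numeric linear predictor, one value per sample.
#' @param surv A [survival_data] object.
#' @return The partial log-likelihood (scalar).
#' @export
partial_loglik <- function(eta, surv) {
  stopifnot(inherits(surv, "survival_data"))
  eta <- as.numeric(eta)
  if (length(eta) != length(surv$time)) {
    stop("eta length must match the number of samples")
  }
  so <- surv_order(surv)
  cpp_partial_loglik(eta[so$ord], so$status, so$group_start)
}
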