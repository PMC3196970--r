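#' Rank genes by absolute Wald ratio
#'
#' Orders the gene universe by `|z|` from largest to smallest, the ranking
#' that the enrichment-score tests walk down. Ties are broken by original
#' gene position (stable sort) so the ranking is deterministic.
#'
#' @param z Numeric Wald ratio per gene (finite).
#' @param gene_ids Unique gene identifiers aligned with `z`.
#' @return A `ranked_genes` object with `gene_ids` (in rank order), `scores`
#'   (`|z|`, nonincreasing) and `signed_scores`.
#' @examples
#' rank_genes(c(0.5, -3, 2), c("g1", "g2", "g3"))
#' @export
rank_genes <- function(z, gene_ids = names(z)) {
  z <- as.numeric(z)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(z))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != length(z)) stop("gene_ids length must match z")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (any(!is.finite(z))) stop("non-finite Wald ratios cannot be ranked")
  ord <- order(-abs(z))  # radix sort: stable, ties keep original order
  structure(list(gene_ids = gene_ids[ord], scores = abs(z)[ord],
                 signed_scores = z[ord]),
            class = "ranked_genes")
}

new_gene_set_stat <- function(statistic, test_name, set_size,
                              details = NULL) {
  structure(list(statistic = statistic, test_name = test_name,
                 set_size = as.integer(set_size), details = details),
            class = "gene_set_stat")
}

#' @export
print.gene_set_stat <- function(x, ...) {
  cat(sprintf("%s statistic = %.6g (set size %d)\n", x$test_name,
              x$statistic, x$set_size))
  invisible(x)
}

#' Kolmogorov-Smirnov-type enrichment score
#'
#' Walks the ranked gene list accumulating a running sum that increases by
#' `|r_j|^w / sum over the set of |r_k|^w` on set members and decreases by
#' `1/(p - m)` on non-members; the statistic is the signed running-sum value
#' of maximal absolute magnitude ("maximum deviation from zero"). With
#' `w = 0` every member contributes `1/m` (the unweighted, classical
#' KS-type score); with `w = 1` members are weighted by their Wald ratio
#' magnitude. The raw maximum deviation is reported without further
#' normalization: inference is by permutation of the same statistic, so any
#' monotone normalization leaves the p-value unchanged.
#'
#' @param ranked A [rank_genes] result over the full gene universe.
#' @param set_members Character vector of gene identifiers in the set.
#' @param w Weight exponent, 0 (unweighted) or 1 (Wald-weighted).
#' @return A `gene_set_stat` (test name `GSEA1` for `w = 0`, `GSEA2` for
#'   `w = 1`) whose `details$path` holds the full running sum.
#' @export
enrichment_score <- function(ranked, set_members, w = 0) {
  stopifnot(inherits(ranked, "ranked_genes"), w %in% c(0, 1))
  p <- length(ranked$gene_ids)
  member <- ranked$gene_ids %in% set_members
  m <- sum(member)
  if (m == 0) stop("gene set not represented in the ranked universe")
  if (m == p) stop("gene set covers the whole universe; decrement undefined")
  if (w == 0) {
    up <- rep(1 / m, m)
  } else {
    wts <- ranked$scores[member]
    tot <- sum(wts)
    if (tot <= 0) stop("w = 1 requires a positive total |r| over the set")
    up <- wts / tot
  }
  steps <- numeric(p)
  steps[member] <- up
  steps[!member] <- -1 / (p - m)
  path <- cumsum(steps)
  es <- path[which.max(abs(path))]
  new_gene_set_stat(es, if (w == 0) "GSEA1" else "GSEA2", m,
                    details = list(path = path, w = w))
}

#' Global Test statistic for survival
#'
#' The score-test quadratic form on martingale residuals:
#' `T = (d - u)' R (d - u) - trace(R U)` with `R = X X'`, `U = diag(u)`,
#' where `d` is the event indicator and `u` the null-model Breslow
#' cumulative hazard at each sample's time. Large `T` indicates that
#' expression of the set is associated with survival. Inference is by
#' subject permutation of `T` itself; the standardized version
#' `(T - mean)/sd` over the permutation replicates is a monotone transform
#' and yields the same permutation p-value.
#'
#' @param X_set Numeric matrix, samples in rows, set genes in columns.
#' @param surv A [survival_data] object.
#' @param cumhaz Optional precomputed [breslow_cumhaz] result for `surv`.
#' @return A `gene_set_stat` with test name `GT`.
#' @export
global_test_stat <- function(X_set, surv, cumhaz = NULL) {
  stopifnot(inherits(surv, "survival_data"), is.matrix(X_set))
  if (nrow(X_set) != length(surv$time)) {
    stop("X_set must have one row per sample")
  }
  if (any(!is.finite(X_set))) stop("X_set contains non-finite values")
  if (is.null(cumhaz)) cumhaz <- breslow_cumhaz(surv)
  u <- cumhaz$cumhaz_at_sample
  r <- surv$status - u
  v <- crossprod(X_set, r)               # X' (d - u), an m-vector
  tr <- sum(rowSums(X_set^2) * u)        # trace(R U) with R = X X'
  new_gene_set_stat(sum(v^2) - tr, "GT", ncol(X_set))
}

#' Wald-type sum-of-squares statistic
#'
#' `W = sum of r_j^2` over the genes in the set, where `r_j` is the
#' univariate Cox Wald ratio of gene j (from [wald_z] or [cox_wald_scan]).
#'
#' @param z_set Numeric Wald ratios for the set genes.
#' @return A `gene_set_stat` with test name `WT` (always nonnegative).
#' @examples
#' wald_type_stat(c(1, -2, 3))  # W = 14
#' @export
wald_type_stat <- function(z_set) {
  z_set <- as.numeric(z_set)
  if (length(z_set) == 0) stop("empty gene set")
  if (any(!is.finite(z_set))) stop("non-finite Wald ratios")
  new_gene_set_stat(sum(z_set^2), "WT", length(z_set))
}

#' Boosting control parameters
#'
#' @param n_steps Number of boosting iterations (M).
#' @param step_size Shrinkage factor in (0, 1] applied to each update.
#' @param offset Optional per-sample offset for the linear predictor;
#'   defaults to all zeros (the partial likelihood is shift-invariant, so an
#'   intercept-only offset is equivalent to zero).
#' @return A `boost_control` list.
#' @export
boost_control <- function(n_steps = 100L, step_size = 0.1, offset = NULL) {
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1L, step_size > 0, step_size <= 1)
  structure(list(n_steps = n_steps, step_size = step_size, offset = offset),
            class = "boost_control")
}

#' Componentwise-linear Cox boosting
#'
#' Functional gradient descent on the Cox partial log-likelihood with
#' componentwise linear least-squares base learners: at each step the
#' eta-gradient is computed, every column of `X_set` is regressed on it by
#' univariate least squares, and the linear predictor moves along the
#' single best-fitting column, scaled by `step_size`.
#'
#' @param X_set Numeric matrix, samples in rows, set genes in columns.
#' @param surv A [survival_data] object.
#' @param control A [boost_control] object.
#' @return A `boost_fit` with `eta` (final predictor, original sample
#'   order), `coef` (accumulated coefficient per set gene), `loglik_path`
#'   (partial log-likelihood after each step), `selected` (column chosen at
#'   each step) and `loglik0` (at the offset).
#' @export
boost_cox <- function(X_set, surv, control = boost_control()) {
  stopifnot(inherits(surv, "survival_data"), is.matrix(X_set),
            inherits(control, "boost_control"))
  n <- length(surv$time)
  if (nrow(X_set) != n) stop("X_set must have one row per sample")
  if (any(!is.finite(X_set))) stop("X_set contains non-finite values")
  offset <- control$offset
  if (is.null(offset)) offset <- numeric(n)
  if (length(offset) != n) stop("offset length must match samples")
  so <- surv_order(surv)
  res <- cpp_boost_cox(X_set[so$ord, , drop = FALSE], so$status,
                       so$group_start, offset[so$ord], control$n_steps,
                       control$step_size)
  eta <- numeric(n)
  eta[so$ord] <- res$eta
  structure(list(eta = eta, coef = as.numeric(res$coef),
                 loglik_path = as.numeric(res$loglik_path),
                 selected = as.integer(res$selected),
                 loglik0 = res$loglik0, offset = offset,
                 control = control),
            class = "boost_fit")
}

#' Global Boost Test statistic
#'
#' The gain in Cox partial log-likelihood achieved by boosting the set's
#' expression on top of the offset:
#' `partial_loglik(eta_hat) - partial_loglik(offset)`. Zero when the set
#' carries no signal; nonnegative on the training data because each
#' boosting step can only improve the objective.
#'
#' @param fit A [boost_cox] result.
#' @param surv The [survival_data] the fit was trained on.
#' @return A `gene_set_stat` with test name `GBST`, `details$n_steps`.
#' @export
gbst_stat <- function(fit, surv) {
  stopifnot(inherits(fit, "boost_fit"), inherits(surv, "survival_data"))
  stat <- partial_loglik(fit$eta, surv) - partial_loglik(fit$offset, surv)
  new_gene_set_stat(stat, "GBST", length(fit$coef),
                    details = list(n_steps = fit$control$n_steps))
}
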