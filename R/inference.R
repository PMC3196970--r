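# Evaluate code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Independent child seeds spawned from one master seed.
spawn_seeds <- function(master_seed, k) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Subject-permutation p-value for an arbitrary statistic
#'
#' Repeatedly permutes the (time, status) pairs jointly against the rows of
#' the expression matrix, recomputes the statistic, and reports the add-one
#' permutation p-value `(1 + count of permuted statistics at least as
#' extreme) / (B + 1)`. The add-one convention guarantees a valid, never
#' exactly zero p-value; the smallest attainable value is `1/(B + 1)`.
#'
#' @param stat_fn Function of `(X, surv)` returning a scalar statistic.
#' @param X Numeric matrix, samples in rows.
#' @param surv A [survival_data] object.
#' @param B Number of permutations (at least 1).
#' @param seed Integer seed for the permutation stream.
#' @param sidedness `"one"` (reject for large values; the default used for
#'   all five gene-set tests) or `"two"` (compare absolute values).
#' @return A `permutation_result` with `observed`, `perm_stats`, `p_value`,
#'   `B` and `seed`.
#' @export
permutation_pvalue <- function(stat_fn, X, surv, B = 1000L, seed = 1L,
                               sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.function(stat_fn), inherits(surv, "survival_data"), B >= 1)
  B <- as.integer(B)
  n <- length(surv$time)
  observed <- stat_fn(X, surv)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n)
      sp <- survival_data(surv$time[idx], surv$status[idx])
      out <- tryCatch(stat_fn(X, sp), error = function(e) e)
      if (inherits(out, "error")) {       # one retry with a fresh draw
        idx <- sample.int(n)
        sp <- survival_data(surv$time[idx], surv$status[idx])
        out <- tryCatch(stat_fn(X, sp), error = function(e) {
          stop(sprintf("statistic failed twice on permutation %d: %s",
                       b, conditionMessage(e)), call. = FALSE)
        })
      }
      as.numeric(out)
    }, numeric(1))
  })
  p <- perm_p_value(observed, perm_stats, sidedness)
  structure(list(observed = observed, perm_stats = perm_stats, p_value = p,
                 B = B, seed = seed, sidedness = sidedness),
            class = "permutation_result")
}

perm_p_value <- function(observed, perm_stats, sidedness) {
  if (sidedness == "two") {
    (1 + sum(abs(perm_stats) >= abs(observed))) / (length(perm_stats) + 1)
  } else {
    (1 + sum(perm_stats >= observed)) / (length(perm_stats) + 1)
  }
}

# All five tests reject for large statistic values. The enrichment scores
# are compared on their signed maximum deviation: because genes are ranked
# by |r|, set members cluster near the TOP of the list under association of
# either sign, driving the running sum positive — so a one-sided comparison
# is the powerful direction for Case A and Case B alike. A two-sided
# comparison on |ES| remains available through permutation_pvalue().
test_sidedness <- function(test) "one"

#' All five gene-set tests on one dataset with shared permutations
#'
#' Computes any subset of the five statistics (GSEA1, GSEA2, GT, WT, GBST)
#' for a single gene set and their subject-permutation p-values. Every
#' requested statistic is evaluated on the SAME permuted datasets, so
#' cross-test comparisons are paired and the genome-wide Cox scan that
#' GSEA and WT share is computed once per permutation.
#'
#' Permuting the (time, status) pairs against the expression rows is
#' implemented by permuting the expression rows against a fixed,
#' time-sorted phenotype — the same group action, which lets the risk-set
#' bookkeeping and the null Breslow cumulative hazard be reused across all
#' permutations.
#'
#' @param X Numeric matrix, samples in rows, the full gene universe in
#'   columns.
#' @param surv A [survival_data] object.
#' @param set_idx Columns of `X` forming the gene set (indices or names).
#' @param tests Character subset of `c("gsea1","gsea2","gt","wt","gbst")`.
#' @param B Number of permutations.
#' @param seed Integer seed for the shared permutation stream.
#' @param boost A [boost_control] for the GBST fit.
#' @param fast_scan Use the single-evaluation score scan for the per-gene
#'   Wald ratios (see [cox_wald_scan]).
#' @return A `set_test_result`: named `statistics`, `p_values`, the
#'   permutation matrix `perm_stats` (B rows), `B`, `seed`.
#' @export
gene_set_test <- function(X, surv, set_idx,
                          tests = c("gsea1", "gsea2", "gt", "wt", "gbst"),
                          B = 1000L, seed = 1L, boost = boost_control(),
                          fast_scan = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(is.matrix(X), inherits(surv, "survival_data"), B >= 1)
  n <- length(surv$time)
  if (nrow(X) != n) stop("X must have one row per sample")
  if (is.character(set_idx)) {
    set_idx <- match(set_idx, colnames(X))
    if (any(is.na(set_idx))) stop("set members missing from X columns")
  }
  set_idx <- as.integer(set_idx)
  p <- ncol(X)
  m <- length(set_idx)
  if (m < 1 || m >= p) stop("gene set must satisfy 1 <= m < p")

  so <- surv_order(surv)
  Xs <- X[so$ord, , drop = FALSE]
  surv_sorted <- survival_data(so$time, so$status)
  cumhaz <- breslow_cumhaz(surv_sorted)
  u <- cumhaz$cumhaz_at_sample
  resid <- so$status - u
  gs0 <- so$group_start
  need_scan <- any(c("gsea1", "gsea2", "wt") %in% tests)
  offset0 <- numeric(n)
  member <- logical(p)
  member[set_idx] <- TRUE

  eval_stats <- function(Xp) {
    out <- numeric(0)
    if (need_scan) {
      scan <- cpp_cox_scan(Xp, so$status, gs0, 25L, 1e-8, 50,
                           isTRUE(fast_scan))
      z <- scan[, 3]
      z[scan[, 6] == 1] <- 0
      if (!isTRUE(fast_scan)) z[scan[, 4] == 0] <- 0
      if (any(c("gsea1", "gsea2") %in% tests)) {
        ord <- order(-abs(z))
        mem_ranked <- member[ord]
        absz <- abs(z)[ord]
        if ("gsea1" %in% tests) {
          out["gsea1"] <- es_from_ranked(mem_ranked, absz, 0, p, m)
        }
        if ("gsea2" %in% tests) {
          out["gsea2"] <- es_from_ranked(mem_ranked, absz, 1, p, m)
        }
      }
      if ("wt" %in% tests) out["wt"] <- sum(z[set_idx]^2)
    }
    if ("gt" %in% tests) {
      Xset <- Xp[, set_idx, drop = FALSE]
      v <- crossprod(Xset, resid)
      out["gt"] <- sum(v^2) - sum(rowSums(Xset^2) * u)
    }
    if ("gbst" %in% tests) {
      bres <- cpp_boost_cox(Xp[, set_idx, drop = FALSE], so$status, gs0,
                            offset0, boost$n_steps, boost$step_size)
      out["gbst"] <- bres$loglik_path[boost$n_steps] - bres$loglik0
    }
    out[tests]
  }

  observed <- eval_stats(Xs)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      eval_stats(Xs[sample.int(n), , drop = FALSE])
    }, numeric(length(tests)))
  })
  perm_stats <- if (length(tests) == 1L) matrix(perm_stats, ncol = 1L) else t(perm_stats)
  colnames(perm_stats) <- tests
  p_values <- vapply(tests, function(tn) {
    perm_p_value(observed[[tn]], perm_stats[, tn], test_sidedness(tn))
  }, numeric(1))
  structure(list(statistics = observed, p_values = p_values,
                 perm_stats = perm_stats, set_size = m, B = B, seed = seed,
                 tests = tests),
            class = "set_test_result")
}

# Running-sum enrichment score on a membership vector already in rank order.
es_from_ranked <- function(mem_ranked, absz_ranked, w, p, m) {
  if (w == 0) {
    up <- rep(1 / m, m)
  } else {
    wts <- absz_ranked[mem_ranked]
    tot <- sum(wts)
    if (tot <= 0) up <- rep(1 / m, m) else up <- wts / tot
  }
  steps <- numeric(p)
  steps[mem_ranked] <- up
  steps[!mem_ranked] <- -1 / (p - m)
  path <- cumsum(steps)
  path[which.max(abs(path))]
}

#' Benjamini-Hochberg FDR over a pathway collection
#'
#' Standard step-up q-values: `q_(i) = min over j >= i of p_(j) * K / j`,
#' capped at 1 (computed via [stats::p.adjust]).
#'
#' @param p_values Numeric p-values, optionally named by pathway.
#' @param threshold Significance threshold on q (default 0.1).
#' @return An `fdr_result` with `p_values`, `q_values`, `threshold` and a
#'   logical `significant` flag per pathway.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p_values, threshold = 0.1) {
  pv <- setNames(as.numeric(p_values), names(p_values))
  if (length(pv) == 0) stop("empty p-value vector")
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- p.adjust(pv, method = "BH")
  structure(list(p_values = pv, q_values = q, threshold = threshold,
                 significant = q < threshold),
            class = "fdr_result")
}
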