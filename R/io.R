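# Structured log line: level, timestamp, module, message.
survgsa_log <- function(level, module, msg) {
  message(sprintf("[%s] %s %s: %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), module, msg))
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a genes x samples expression table
#'
#' Expects a TSV (or CSV, by file extension) with gene identifiers in the
#' first column and one header column per sample. Genes containing missing
#' or non-numeric values are handled per `na_policy`.
#'
#' @param path Path to the table.
#' @param na_policy `"drop_gene"` (default: drop offending genes with a
#'   warning) or `"error"` (fail, reporting the first offending gene and
#'   sample).
#' @return A numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @export
read_expression <- function(path, na_policy = c("drop_gene", "error")) {
  na_policy <- match.arg(na_policy)
  df <- read_table_auto(path)
  if (ncol(df) < 3) stop("expression table needs a gene column and at least 2 samples")
  gene_ids <- as.character(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in header")
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (na_policy == "error") {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                   gene_ids[idx[1]], sample_ids[idx[2]]))
    }
    drop_genes <- unique(gene_ids[which(bad, arr.ind = TRUE)[, 1]])
    warning(sprintf("dropping %d gene(s) with missing values: %s",
                    length(drop_genes),
                    paste(utils::head(drop_genes, 5), collapse = ", ")))
    survgsa_log("WARN", "io", sprintf("dropped %d gene(s) under na_policy=drop_gene",
                                      length(drop_genes)))
    vals <- vals[!(gene_ids %in% drop_genes), , drop = FALSE]
  }
  if (nrow(vals) == 0) stop("no genes left after NA filtering")
  vals
}

#' Read a per-sample survival table
#'
#' Expects columns `sample_id`, `time`, `status` (TSV or CSV by
#' extension).
#'
#' @param path Path to the table.
#' @return A [survival_data] object.
#' @export
read_survival <- function(path) {
  df <- read_table_auto(path)
  need <- c("sample_id", "time", "status")
  if (!all(need %in% colnames(df))) {
    stop("survival table needs columns sample_id, time, status")
  }
  status <- suppressWarnings(as.numeric(df$status))
  time <- suppressWarnings(as.numeric(df$time))
  if (any(is.na(status)) || !all(status %in% c(0, 1))) {
    stop("status must be 0 or 1")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all times must be positive")
  }
  survival_data(time, status, sample_ids = df$sample_id)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are deduplicated with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection` with named `sets`, `descriptions` and
#'   `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file")
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", i))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stop(sprintf("duplicate set name '%s'", nm))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d ('%s') has an empty member list", i, nm))
    }
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': %d duplicate member(s) removed", nm,
                      sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[nm]] <- members
    descriptions[nm] <- fields[2]
  }
  structure(list(sets = sets, descriptions = descriptions, source = path),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d) from %s\n",
              length(x$sets), min(sizes), max(sizes), x$source))
  invisible(x)
}

# Deterministic checksum of a configuration list (plain polynomial
# checksum over the deparsed text; for provenance stamping, not crypto).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  v <- as.numeric(utf8ToInt(s))
  sprintf("%08x", as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 2^31))
}

#' Run all gene-set tests over a pathway collection
#'
#' For every pathway: intersect members with the expression genes (missing
#' members are dropped with a warning), skip pathways smaller than
#' `min_set_size`, compute the requested statistics, permutation p-values
#' on one shared subject-permutation stream (every statistic and every
#' pathway sees the same permuted datasets), and Benjamini-Hochberg
#' q-values per test across the analyzed pathways.
#'
#' @param expr Genes x samples numeric matrix (e.g. [read_expression]).
#' @param surv A [survival_data]; sample ids must match `colnames(expr)`.
#' @param sets A `gene_set_collection` from [read_gmt], or a named list of
#'   gene-id vectors.
#' @param tests Character subset of the five tests.
#' @param B Permutations.
#' @param seed Integer seed for the shared permutation stream.
#' @param min_set_size Smallest analyzable pathway (after intersection).
#' @param fdr_threshold Threshold on BH q-values.
#' @param boost [boost_control] for GBST.
#' @param fast_scan Score-statistic scan (see [cox_wald_scan]).
#' @param allow_subset Permit survival samples absent from the expression
#'   matrix (they are dropped); by default this is an error.
#' @return A `survgsa_results` data.frame with one row per
#'   (pathway, test): `pathway`, `test`, `set_size_used`, `statistic`,
#'   `p_value`, `q_value`, `significant`; attributes `seed`, `B`,
#'   `version`, `config_hash`, `fdr_threshold`.
#' @export
run_analysis <- function(expr, surv, sets,
                         tests = c("gsea1", "gsea2", "gt", "wt", "gbst"),
                         B = 1000L, seed = 1L, min_set_size = 5L,
                         fdr_threshold = 0.1, boost = boost_control(),
                         fast_scan = FALSE, allow_subset = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(is.matrix(expr), inherits(surv, "survival_data"), B >= 19)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named")
  }
  missing_samples <- setdiff(surv$sample_ids, colnames(expr))
  if (length(missing_samples) > 0 && !allow_subset) {
    stop(sprintf("survival sample(s) missing from expression matrix: %s",
                 paste(utils::head(missing_samples, 10), collapse = ", ")))
  }
  keep <- surv$sample_ids %in% colnames(expr)
  if (!all(keep)) {
    survgsa_log("WARN", "io",
                sprintf("dropping %d survival sample(s) without expression",
                        sum(!keep)))
    surv <- survival_data(surv$time[keep], surv$status[keep],
                          surv$sample_ids[keep])
  }
  X <- t(expr[, surv$sample_ids, drop = FALSE])   # samples x genes
  gene_ids <- colnames(X)
  p <- ncol(X)
  n <- nrow(X)

  set_idx <- list()
  for (nm in names(sets)) {
    found <- intersect(sets[[nm]], gene_ids)
    n_missing <- length(setdiff(sets[[nm]], gene_ids))
    if (n_missing > 0) {
      warning(sprintf("set '%s': %d member(s) absent from the expression matrix",
                      nm, n_missing))
    }
    if (length(found) < min_set_size) {
      survgsa_log("INFO", "io",
                  sprintf("skipping set '%s' (%d usable genes < min_set_size %d)",
                          nm, length(found), min_set_size))
      next
    }
    if (length(found) >= p) {
      survgsa_log("INFO", "io",
                  sprintf("skipping set '%s' (covers the whole universe)", nm))
      next
    }
    set_idx[[nm]] <- match(found, gene_ids)
  }
  if (length(set_idx) == 0) stop("zero analyzable pathways")

  so <- surv_order(surv)
  Xs <- X[so$ord, , drop = FALSE]
  surv_sorted <- survival_data(so$time, so$status)
  u <- breslow_cumhaz(surv_sorted)$cumhaz_at_sample
  resid <- so$status - u
  gs0 <- so$group_start
  need_scan <- any(c("gsea1", "gsea2", "wt") %in% tests)
  offset0 <- numeric(n)

  eval_all <- function(Xp) {
    z <- NULL
    ord <- NULL
    if (need_scan) {
      scan <- cpp_cox_scan(Xp, so$status, gs0, 25L, 1e-8, 50,
                           isTRUE(fast_scan))
      z <- scan[, 3]
      z[scan[, 6] == 1] <- 0
      if (!isTRUE(fast_scan)) z[scan[, 4] == 0] <- 0
      ord <- order(-abs(z))
    }
    out <- matrix(NA_real_, length(set_idx), length(tests),
                  dimnames = list(names(set_idx), tests))
    for (si in seq_along(set_idx)) {
      idx <- set_idx[[si]]
      m <- length(idx)
      if (need_scan && any(c("gsea1", "gsea2") %in% tests)) {
        member <- logical(p)
        member[idx] <- TRUE
        mem_ranked <- member[ord]
        absz <- abs(z)[ord]
        if ("gsea1" %in% tests) {
          out[si, "gsea1"] <- es_from_ranked(mem_ranked, absz, 0, p, m)
        }
        if ("gsea2" %in% tests) {
          out[si, "gsea2"] <- es_from_ranked(mem_ranked, absz, 1, p, m)
        }
      }
      if ("wt" %in% tests) out[si, "wt"] <- sum(z[idx]^2)
      if ("gt" %in% tests) {
        Xset <- Xp[, idx, drop = FALSE]
        v <- crossprod(Xset, resid)
        out[si, "gt"] <- sum(v^2) - sum(rowSums(Xset^2) * u)
      }
      if ("gbst" %in% tests) {
        bres <- cpp_boost_cox(Xp[, idx, drop = FALSE], so$status, gs0,
                              offset0, boost$n_steps, boost$step_size)
        out[si, "gbst"] <- bres$loglik_path[boost$n_steps] - bres$loglik0
      }
    }
    out
  }

  observed <- eval_all(Xs)
  B <- as.integer(B)
  perm <- with_seed(seed, {
    arr <- array(NA_real_, c(length(set_idx), length(tests), B))
    for (b in seq_len(B)) {
      arr[, , b] <- eval_all(Xs[sample.int(n), , drop = FALSE])
    }
    arr
  })
  pvals <- matrix(NA_real_, length(set_idx), length(tests),
                  dimnames = dimnames(observed))
  for (si in seq_along(set_idx)) {
    for (ti in seq_along(tests)) {
      pvals[si, ti] <- perm_p_value(observed[si, ti], perm[si, ti, ],
                                    test_sidedness(tests[ti]))
    }
  }
  qvals <- apply(pvals, 2, function(pcol) bh_fdr(pcol, fdr_threshold)$q_values)
  qvals <- matrix(qvals, nrow = nrow(pvals), dimnames = dimnames(pvals))

  res <- do.call(rbind, lapply(seq_along(set_idx), function(si) {
    data.frame(pathway = names(set_idx)[si], test = tests,
               set_size_used = length(set_idx[[si]]),
               statistic = observed[si, ], p_value = pvals[si, ],
               q_value = qvals[si, ],
               significant = qvals[si, ] < fdr_threshold,
               row.names = NULL)
  }))
  cfg <- list(tests = tests, B = B, seed = seed,
              min_set_size = min_set_size, fdr_threshold = fdr_threshold,
              n_samples = n, n_genes = p,
              boost = boost[c("n_steps", "step_size")],
              fast_scan = isTRUE(fast_scan))
  attr(res, "seed") <- seed
  attr(res, "B") <- B
  attr(res, "version") <- as.character(packageVersion("survgsa"))
  attr(res, "config_hash") <- config_hash(cfg)
  attr(res, "fdr_threshold") <- fdr_threshold
  class(res) <- c("survgsa_results", "data.frame")
  res
}

#' Write a results table with its reproducibility metadata
#'
#' Writes a TSV whose `#`-prefixed header lines record the seed,
#' permutation count, package version and configuration hash needed to
#' reproduce the run exactly.
#'
#' @param results A `survgsa_results` from [run_analysis].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "survgsa_results"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# survgsa %s | seed=%d | B=%d | config=%s | fdr<%g",
                     attr(results, "version"), attr(results, "seed"),
                     attr(results, "B"), attr(results, "config_hash"),
                     attr(results, "fdr_threshold")), con)
  write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset in the analysis input formats
#'
#' Emits `<prefix>_expression.tsv` (genes x samples),
#' `<prefix>_survival.tsv` (sample_id, time, status) and
#' `<prefix>_sets.gmt` (the tested gene set), so the full file-based
#' analysis path can be exercised on synthetic data.
#'
#' @param sim A `sim_dataset` from [simulate_dataset].
#' @param prefix Output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_dataset"))
  expr_path <- paste0(prefix, "_expression.tsv")
  surv_path <- paste0(prefix, "_survival.tsv")
  gmt_path <- paste0(prefix, "_sets.gmt")
  expr <- t(sim$X)                               # genes x samples on disk
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = sim$surv$sample_ids,
                         time = sim$surv$time, status = sim$surv$status),
              surv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  members <- colnames(sim$X)[sim$set_idx]
  writeLines(paste(c("tested_set", "simulated gene set", members),
                   collapse = "\t"), gmt_path)
  invisible(c(expression = expr_path, survival = surv_path,
              gmt = gmt_path))
}
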