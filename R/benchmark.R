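#' Scenario grid for size / power experiments
#'
#' Bundles the simulation cells with the Monte-Carlo budget used to
#' estimate empirical size and power: number of replications, permutations
#' per replication, nominal level, and the tests to run.
#'
#' @param cells A list of [sim_config] objects (a single config is
#'   wrapped).
#' @param n_reps Replications per cell.
#' @param B Permutations per replication (at least 19, the minimum giving
#'   p-value resolution below 0.05).
#' @param alpha Nominal level.
#' @param tests Character subset of the five tests.
#' @param boost [boost_control] passed to the GBST fits.
#' @param fast_scan Use the score-statistic scan for per-gene Wald ratios.
#' @return A `scenario_grid`.
#' @export
scenario_grid <- function(cells, n_reps = 100L, B = 200L, alpha = 0.05,
                          tests = c("gsea1", "gsea2", "gt", "wt", "gbst"),
                          boost = boost_control(), fast_scan = FALSE) {
  if (inherits(cells, "sim_config")) cells <- list(cells)
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "sim_config")),
            n_reps >= 1, B >= 19, alpha > 0, alpha < 1)
  tests <- match.arg(tests, several.ok = TRUE)
  structure(list(cells = cells, n_reps = as.integer(n_reps),
                 B = as.integer(B), alpha = alpha, tests = tests,
                 boost = boost, fast_scan = isTRUE(fast_scan)),
            class = "scenario_grid")
}

# Shared engine behind estimate_size / estimate_power: per cell, realize the
# covariance once, then run n_reps independent replications (fresh
# coefficients, expression and survival per replication; all five statistics
# evaluated on the same permuted datasets within a replication).
run_grid <- function(grid, seed, mc_size = 10000L) {
  t0 <- Sys.time()
  cell_seeds <- spawn_seeds(seed, length(grid$cells))
  rows <- list()
  for (ci in seq_along(grid$cells)) {
    cfg <- grid$cells[[ci]]
    seeds <- spawn_seeds(cell_seeds[ci], grid$n_reps + 1L)
    cov <- build_covariance(cfg$cov_case, cfg$p, cfg$m,
                            if (cfg$coef_case == "null") 0 else cfg$m_p,
                            seed = seeds[grid$n_reps + 1L])
    rej <- matrix(NA, grid$n_reps, length(grid$tests),
                  dimnames = list(NULL, grid$tests))
    n_failed <- 0L
    for (r in seq_len(grid$n_reps)) {
      res <- tryCatch({
        ds <- simulate_dataset(cfg, seed = seeds[r], cov = cov,
                               mc_size = mc_size)
        gene_set_test(ds$X, ds$surv, ds$set_idx, tests = grid$tests,
                      B = grid$B, seed = seeds[r], boost = grid$boost,
                      fast_scan = grid$fast_scan)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        warning(sprintf("cell %d replication %d failed: %s", ci, r,
                        conditionMessage(res)))
        next
      }
      rej[r, ] <- res$p_values < grid$alpha
    }
    done <- grid$n_reps - n_failed
    rate <- colMeans(rej, na.rm = TRUE)
    rows[[ci]] <- data.frame(
      cov_case = cfg$cov_case, coef_case = cfg$coef_case, p = cfg$p,
      n = cfg$n, m = cfg$m, m_p = cfg$m_p, c_p = cfg$c_p,
      test = grid$tests, rejection_rate = as.numeric(rate),
      mc_se = sqrt(rate * (1 - rate) / done),
      n_reps_completed = done, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- grid$alpha
  attr(out, "B") <- grid$B
  attr(out, "seed") <- seed
  attr(out, "runtime_sec") <- as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))
  class(out) <- c("size_power_table", "data.frame")
  out
}

#' Estimate empirical size (type-I error)
#'
#' Runs every cell of the grid under the global null (all survival
#' coefficients zero) and reports, per cell and test, the proportion of
#' replications with permutation p-value below the nominal level, with its
#' binomial Monte-Carlo standard error.
#'
#' @param grid A [scenario_grid]; every cell must have
#'   `coef_case = "null"`.
#' @param seed Master seed; each cell and replication receives an
#'   independent child seed.
#' @param mc_size Monte-Carlo size for censoring calibration.
#' @return A `size_power_table` data.frame (one row per cell x test) with
#'   attributes `alpha`, `B`, `seed`, `runtime_sec`.
#' @export
estimate_size <- function(grid, seed = 1L, mc_size = 10000L) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (!all(vapply(grid$cells, function(c) c$coef_case == "null",
                  logical(1)))) {
    stop("size estimation requires every cell to use coef_case = 'null'")
  }
  run_grid(grid, seed, mc_size)
}

#' Estimate empirical power
#'
#' Runs every cell of the grid under the alternative (coefficient Case A
#' or B) and reports rejection proportions at the nominal level. An
#' optional `m_p_sweep` expands every cell across several proportions of
#' significant genes, the effect-size axis of the power curves.
#'
#' @inheritParams estimate_size
#' @param m_p_sweep Optional numeric vector of `m_p` values expanding each
#'   cell.
#' @return A `size_power_table` data.frame.
#' @export
estimate_power <- function(grid, seed = 1L, m_p_sweep = NULL,
                           mc_size = 10000L) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (!all(vapply(grid$cells, function(c) c$coef_case %in% c("A", "B"),
                  logical(1)))) {
    stop("power estimation requires coef_case 'A' or 'B' in every cell")
  }
  if (!is.null(m_p_sweep)) {
    cells <- unlist(lapply(grid$cells, function(cfg) {
      lapply(m_p_sweep, function(mp) {
        sim_config(cfg$p, cfg$n, cfg$m, mp, cfg$c_p, cfg$cov_case,
                   cfg$coef_case, cfg$baseline_rate)
      })
    }), recursive = FALSE)
    grid$cells <- cells
  }
  run_grid(grid, seed, mc_size)
}

#' Read a benchmark configuration from YAML
#'
#' Expected layout: top-level `n_reps`, `B`, `alpha`, `tests`, `fast_scan`
#' and a `cells` list whose entries hold [sim_config] fields.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_grid].
#' @export
read_benchmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cells)) stop("benchmark config needs a 'cells' list")
  cells <- lapply(cfg$cells, function(cc) {
    # YAML 1.1 implicit typing turns a bare `n:` key into a boolean;
    # map it back (quote 'n' in the file to avoid this entirely)
    names(cc)[names(cc) %in% c("FALSE", "false", "no")] <- "n"
    do.call(sim_config, cc)
  })
  scenario_grid(cells,
                n_reps = cfg$n_reps %||% 100L,
                B = cfg$B %||% 200L,
                alpha = cfg$alpha %||% 0.05,
                tests = cfg$tests %||% c("gsea1", "gsea2", "gt", "wt", "gbst"),
                fast_scan = cfg$fast_scan %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Power curves over the proportion of significant genes
#'
#' Plots rejection rate against `m_p` per test and cell (requires ggplot2).
#'
#' @param table A `size_power_table` from [estimate_power].
#' @return A ggplot object.
#' @export
plot_power_curves <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- as.data.frame(table)
  df$cell <- sprintf("Case %s/%s, c_p=%g", df$cov_case, df$coef_case,
                     df$c_p)
  ggplot2::ggplot(df, ggplot2::aes(x = m_p, y = rejection_rate,
                                   colour = test)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "proportion of significant genes (m_p)",
                  y = "rejection rate") +
    ggplot2::theme_bw()
}
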