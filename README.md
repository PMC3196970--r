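# survgsa — gene-set analysis for censored survival phenotypes

`survgsa` tests whether the expression of an a priori defined gene set
(pathway) is associated with censored patient survival. It is aimed at
transcriptomics analysts who have a genes × samples expression matrix, a
per-sample survival table (follow-up time, event status), and a pathway
collection in GMT format — and at methodologists who want a calibrated
simulation bench for comparing pathway-level survival tests.

## The five tests

All tests build on the Cox proportional-hazards model
`h(t|x) = h0(t) exp(βx)` and share one inference engine:
subject-permutation p-values (the `(time, status)` pairs are permuted
jointly against the expression rows, `B` times), with Benjamini–Hochberg
FDR control across pathways.

| test | statistic |
|---|---|
| GSEA1 | running-sum enrichment score over genes ranked by the absolute Cox Wald ratio r_j = b_j/s_j; equal member increments 1/m (unweighted, KS-type); statistic is the maximum deviation from zero |
| GSEA2 | same running sum with member increments \|r_j\| / Σ_{k∈S}\|r_k\| (association-weighted) |
| GT | Global Test score form on martingale residuals: T = (d − û)′XX′(d − û) − trace(XX′ diag(û)), with û the null-model Breslow cumulative hazard |
| WT | Wald-type sum of squares W = Σ_{j∈S} r_j² |
| GBST | Global Boost Test: gain in Cox partial log-likelihood after componentwise-linear boosting (M = 100 steps, shrinkage ν = 0.1) of the set's expression |

GT, WT and GBST are self-contained subject-sampling tests; the enrichment
scores are rank-based hybrids evaluated under the same subject-sampling
null. A simulation module generates correlated multivariate-normal
expression (four covariance regimes), Cox survival times with constant
baseline hazard 0.005, and exponential censoring calibrated to a target
censoring fraction, and a benchmark module estimates empirical size and
power of all five tests with Monte-Carlo standard errors. See the
methods vignette (`vignettes/gene-set-survival-tests.Rmd`) for the models,
conventions and numerical choices.

## Worked example

Simulate one dataset under a strong alternative — 200 genes, 80 patients,
a tested set of 50 genes of which 25 carry positive Cox coefficients
U(0.2, 0.6), exchangeable correlation among the significant genes, and a
30% target censoring fraction — then run all five tests:

```r
library(survgsa)

cfg <- sim_config(p = 200, n = 80, m = 50, m_p = 0.5, c_p = 0.3,
                  cov_case = "II", coef_case = "A")
ds <- simulate_dataset(cfg, seed = 42)
ds$surv
#> survival_data: 80 samples, 57 events (28.7% censored)

res <- gene_set_test(ds$X, ds$surv, ds$set_idx, B = 1000, seed = 1)
round(res$statistics, 3)
#>    gsea1    gsea2       gt       wt     gbst
#>    0.460    0.730 1932.922  245.098   41.203
round(res$p_values, 4)
#> gsea1 gsea2    gt    wt  gbst
#> 0.001 0.001 0.001 0.001 0.001
```

The realized censoring (28.7%) sits at the calibrated 30% target. Every
statistic is extreme relative to its permutation distribution — the
enrichment score 0.46 means the running sum climbs nearly half its
possible range before set members are exhausted; the GT, WT and GBST
values are only interpretable against their permutation nulls, and all
five reach the smallest attainable add-one p-value 1/(B+1) ≈ 0.001.

Screening a small pathway collection, with BH q-values per test:

```r
set.seed(2)
sets <- c(list(signal = colnames(ds$X)[1:50]),
          setNames(lapply(1:5, function(i) sample(colnames(ds$X)[51:200], 30)),
                   paste0("background_", 1:5)))
tab <- run_analysis(t(ds$X), ds$surv, sets, tests = c("gt", "wt", "gbst"),
                    B = 1000, seed = 3)
subset(as.data.frame(tab), test == "gt")
#>         pathway test set_size_used    statistic     p_value     q_value significant
#> 1        signal   gt            50 1932.9223351 0.000999001 0.005994006        TRUE
#> 4  background_1   gt            30  -52.3538626 0.640359640 0.810189810       FALSE
#> 7  background_2   gt            30  -82.0594849 0.810189810 0.810189810       FALSE
#> 10 background_3   gt            30  -31.9425759 0.545454545 0.810189810       FALSE
#> 13 background_4   gt            30  -62.9949755 0.707292707 0.810189810       FALSE
#> 16 background_5   gt            30    0.9492005 0.406593407 0.810189810       FALSE
```

Only the planted pathway survives the q < 0.1 screen. File-based workflows
use `read_expression()`, `read_survival()`, `read_gmt()` and
`write_results()`; a thin command-line wrapper lives at
`inst/cli/survgsa` (`survgsa run|simulate|benchmark`). Size/power
experiments are driven by `scenario_grid()`, `estimate_size()`,
`estimate_power()` and plotted with `plot_power_curves()`.

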