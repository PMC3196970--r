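---
title: "Gene-set tests for censored survival phenotypes: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set tests for censored survival phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survgsa)
```

## The problem

Pathway-level analysis asks whether the expression of an a priori defined
set of genes is associated with a phenotype, rather than testing genes one
at a time. When the phenotype is censored survival — follow-up time $t_i$
and event indicator $\delta_i$ per patient — the natural per-gene
association measure comes from the Cox proportional-hazards model
$h(t \mid x) = h_0(t)\,e^{\beta x}$, and the pathway-level question becomes
whether any combination of the $m$ genes in a set carries hazard
information. `survgsa` implements five tests of this null hypothesis and a
simulation framework for studying their operating characteristics.

All five tests share one inference engine: subject-level permutation.
The $(t_i, \delta_i)$ pairs are permuted jointly against the expression
rows, every statistic is recomputed on each permuted dataset, and the
p-value is the add-one proportion $(1 + \#\{b : S_b \ge S_{\mathrm{obs}}\})
/ (B + 1)$. This is a *self-contained* (subject-sampling) null for GT, WT
and GBST; the enrichment scores are rank-based statistics whose p-values
are nevertheless computed under the same subject-sampling scheme.

## The five statistics

**Enrichment scores (GSEA1, GSEA2).** Every gene in the universe of size
$p$ gets a Wald ratio $r_j = b_j / s_j$ from its univariate Cox fit; genes
are ranked by $|r_j|$ descending. A running sum increases by
$|r_j|^w / \sum_{k \in S} |r_k|^w$ on set members and decreases by
$1/(p-m)$ otherwise; the statistic is the signed value of maximal absolute
magnitude. $w = 0$ gives the unweighted, Kolmogorov–Smirnov-type score
(GSEA1); $w = 1$ weights members by their association strength (GSEA2).
Two numerical conventions matter and are deliberate:

* *No further normalization of the running-sum maximum.* Any monotone
  rescaling (such as the classical $\sqrt{m(p-m)/p}$ KS factor) leaves a
  permutation p-value unchanged, so the raw maximum deviation is used.
* *One-sided permutation comparison on the signed maximum deviation.*
  Because ranking is by $|r_j|$, set members concentrate near the **top**
  of the list whenever the set is associated with survival — in either
  direction — so the signed score is driven positive under the
  alternative regardless of the sign of the underlying coefficients. A
  one-sided comparison is therefore the powerful direction for both
  positive-coefficient and mixed-sign regimes, and in our calibration
  experiments it reproduces the reference operating characteristics of
  the unweighted score, whereas a two-sided comparison on $|ES|$ loses
  roughly half the rejections in non-saturated cells. A two-sided version
  remains available through `permutation_pvalue(sidedness = "two")`.

**Global Test (GT).** The score-test quadratic form on martingale
residuals,
$T = (d - \hat u)' X X' (d - \hat u) - \mathrm{trace}(X X' \hat U)$,
where $\hat u$ is the *null-model* Breslow cumulative hazard evaluated at
each subject's follow-up time and $\hat U = \mathrm{diag}(\hat u)$. The
standardized form $(T - \hat E T)/\sqrt{\widehat{\mathrm{Var}} T}$ is a
monotone transform of $T$ given the data, so permutation inference is run
on $T$ directly; permutation-estimated moments are available from the
returned permutation statistics if a standardized value is wanted. The
random-effects variance $\tau^2$ that motivates this score test is purely
a hypothesis parameter ($H_0: \tau^2 = 0$) and is never estimated.

**Wald-type test (WT).** $W = \sum_{j \in S} r_j^2$, the sum of squared
univariate Wald ratios over the set.

**Global Boost Test (GBST).** Componentwise-linear boosting of the Cox
partial log-likelihood
$\ell(\eta) = \sum_i \delta_i [\eta_i - \log \sum_{j: t_j \ge t_i}
e^{\eta_j}]$: at each of $M$ steps the gradient with respect to $\eta$ is
computed, each set gene is regressed on it by univariate least squares,
and $\eta$ moves along the best-fitting gene scaled by $\nu$. Defaults are
the conventional componentwise-boosting settings $M = 100$, $\nu = 0.1$.
The permutation statistic is the boosted gain in partial log-likelihood,
$\ell(\hat\eta) - \ell(\text{offset})$ — zero when the set carries no
signal, nonnegative on training data, and monotone in the fitted
objective. Since the partial likelihood is invariant to adding a constant
to $\eta$ (tested to $10^{-10}$), an intercept-only offset is equivalent
to an all-zero offset, which is the default.

## Cox fitting numerics

Univariate fits use Newton–Raphson on the partial-likelihood score with
Breslow tie handling, step-halving whenever a step would decrease the
objective, convergence at $|U(b)| < 10^{-8}$, at most 25 iterations, and a
divergence guard at $|b| > 50$ (monotone likelihoods, e.g. perfect
separation of events, are flagged non-converged). Standard errors come
from the observed information. Genome-wide scans never abort on a
pathological gene: constant or non-converged genes get $r_j = 0$ with a
warning, so a ranking step always receives a complete vector. A
`fast_scan` option replaces the Newton fit by the score statistic at
$b = 0$ ($z = U(0)/\sqrt{I(0)}$), a cheaper, permutation-valid
approximation for very large scans; full Newton fitting is the default
everywhere, including the shipped experiments.

Risk sets use the $t_j \ge t_i$ (Breslow) convention throughout, matching
the partial-likelihood form above. Simulated survival times are continuous
so ties have probability zero there, but the implementation handles tied
times correctly (verified against an independent reference fitter on tied
fixtures).

## The simulator: what it emulates, and what it does not

Expression is drawn $MVN(0, \Sigma)$ with marginal variance $0.2$ and four
correlation structures among the first $k = \lfloor m \cdot m_p \rfloor$
("significant") genes: independent (I), exchangeable $\sigma_{ij} = 0.02$
(II), autoregressive $\sigma_{ij} = 0.2 \times 0.1^{|i-j|}$ (III), and
unstructured $\sigma_{ij} = 0.2\,\rho_{ij}$, $\rho_{ij} \sim N(0, 0.1^2)$
(IV). A Case IV realization can be indefinite when the significant block
is large; it is repaired by clipping eigenvalues at $10^{-8}$ and
re-symmetrizing, and the repair is always reported. The realization is
fixed per scenario; coefficients are redrawn per replication.

Survival times follow the Cox model with constant baseline hazard
$h_0 = 0.005$ by inverse transform,
$T_i = -\log U_i / (h_0 e^{\beta' X_i})$. Coefficients are
$U(0.2, 0.6)$ on the significant genes (Case A, one-directional) or
$N(0, 0.5^2)$ (Case B, mixed-sign), zero elsewhere. Censoring is an
independent exponential competing time whose rate is *calibrated*: the
per-subject censoring probability under competing exponentials is
$\lambda / (\lambda + h(X))$, so $\lambda$ solves
$E_X[\lambda/(\lambda + h(X))] = c_p$ — in closed form
$\lambda = h_0\, c_p/(1 - c_p)$ when $\beta = 0$, otherwise by
root-finding over a Monte-Carlo approximation of the expectation (10,000
fresh draws by default; the round-trip calibration error is under 0.03 in
the shipped tests). The tested set is always genes $1..m$ of the universe;
exactly one set is evaluated per simulated dataset.

What this generator does **not** emulate: non-Gaussian and heavy-tailed
expression, non-constant baseline hazards, dependent or covariate-driven
censoring, measurement error, and between-pathway overlap. Passing tests
on this generator therefore demonstrate correctness of the statistics and
calibration of the permutation inference under the stated model, not
robustness to the full messiness of real transcriptomic survival data.

## Size and power experiments

`estimate_size()` and `estimate_power()` orchestrate the replication
loops: per cell, `n_reps` independent datasets; per dataset, all requested
statistics evaluated on the *same* $B$ permuted datasets (a paired design
that removes between-test permutation noise from cross-test comparisons);
rejection proportions at $\alpha = 0.05$ with binomial Monte-Carlo
standard errors $\sqrt{r(1-r)/n_{\mathrm{reps}}}$.

The package's own experiments run at desk scale — 100 replications for
size, 50–100 for power, $B = 200$ permutations, $p = 200$ genes, $n = 80$
subjects, $m = 50$ — sizes chosen so the full suite completes in minutes
on one core while keeping Monte-Carlo standard errors near 0.02–0.05.
Full-scale settings (500/200 replications, $B = 1000$) are a
`scenario_grid(n_reps =, B =)` call away. At desk scale the qualitative
findings are stable across seeds: the empirical size of all five tests
sits at the nominal 0.05; GT, WT and GBST dominate both enrichment scores
in every power cell; power falls as censoring rises; and one-directional
coefficients on positively correlated genes (Cases II/IV with A) push all
five tests toward power 1 — the synergy between within-set correlation
and one-directional association.

## Degenerate inputs and tie-breaks

* Ranking ties in $|r_j|$ are broken by original gene position (stable
  sort), so rankings are deterministic.
* If every member weight is zero in the $w = 1$ score (all set genes
  degenerate), the score falls back to equal weights inside the
  permutation engine; the user-facing `enrichment_score()` raises instead,
  since a zero total weight almost always signals an upstream problem.
* A gene set must satisfy $1 \le m < p$: the decrement $1/(p - m)$ is
  undefined at $m = p$, and an empty intersection with the expression
  universe is an error, not a silent skip. In `run_analysis()`, pathways
  whose usable intersection falls below `min_set_size` (default 5, the
  smallest pathway size we consider informative) are skipped with a logged
  message.
* All-zero expression for a set yields GT $= 0$, GBST $= 0$ and a
  coefficient vector that never moves — valid degenerate values, not
  errors, so screening runs survive pathological pathways.
* The add-one p-value estimator guarantees $p \ge 1/(B+1) > 0$, and B
  must be at least 19 for any rejection at $\alpha = 0.05$ to be possible.

## Reproducibility machinery

Every stochastic entry point takes a seed; a master seed spawns
independent child seeds per cell and per replication, and the RNG state of
the calling session is always restored. Results tables carry the seed,
permutation count, package version and a configuration checksum in their
metadata; `write_results()` persists them in the file header. Simulated
datasets round-trip through the TSV/GMT readers bit-for-bit into the same
analysis results.

## Known limitations

* Clinical-covariate adjustment (a fitted offset for GBST, nuisance
  covariates for GT/WT) is not implemented; all tests condition on
  expression alone.
* Ties are handled by the Breslow convention only; Efron weighting is out
  of scope.
* The GT statistic is reported unstandardized (permutation inference
  makes the standardization immaterial); users comparing raw $T$ values
  across datasets should standardize by the permutation moments
  themselves.
* Gene-sampling ("competitive") null hypotheses are intentionally absent:
  all five tests here are evaluated under subject permutation.
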