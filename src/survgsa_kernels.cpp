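#include <Rcpp.h>
using namespace Rcpp;

// All kernels assume samples sorted by increasing follow-up time.
// group_start[i] is the 0-based index of the first sample tied with i
// (Breslow convention: the risk set of an event at t is every sample with
// time >= t, so tied samples share one risk set starting at group_start).

static double suffix_loglik(const double* eta, const int* status,
                            const int* group_start, int n, double* s0buf) {
  double shift = R_NegInf;
  for (int i = 0; i < n; ++i) if (eta[i] > shift) shift = eta[i];
  if (!R_FINITE(shift)) shift = 0.0;
  s0buf[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) s0buf[i] = s0buf[i + 1] + std::exp(eta[i] - shift);
  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    if (status[i] == 1) ll += (eta[i] - shift) - std::log(s0buf[group_start[i]]);
  return ll;
}

// [[Rcpp::export]]
double cpp_partial_loglik(NumericVector eta, IntegerVector status,
                          IntegerVector group_start) {
  const int n = eta.size();
  std::vector<double> s0(n + 1);
  return suffix_loglik(eta.begin(), status.begin(), group_start.begin(), n,
                       s0.data());
}

// Score, information and log-likelihood of the univariate Cox partial
// likelihood at coefficient b, in one pass of suffix sums. Buffers are
// caller-allocated (length n + 1) so genome-wide scans do not churn memory.
static void cox_uvs(const double* x, const int* status,
                    const int* group_start, int n, double b,
                    double& U, double& I, double& ll,
                    double* s0, double* s1, double* s2) {
  double shift = R_NegInf;
  for (int i = 0; i < n; ++i) { double e = b * x[i]; if (e > shift) shift = e; }
  if (!R_FINITE(shift)) shift = 0.0;
  s0[n] = 0.0; s1[n] = 0.0; s2[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    double w = std::exp(b * x[i] - shift);
    s0[i] = s0[i + 1] + w;
    s1[i] = s1[i + 1] + w * x[i];
    s2[i] = s2[i + 1] + w * x[i] * x[i];
  }
  U = 0.0; I = 0.0; ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (status[i] != 1) continue;
    int g = group_start[i];
    double m1 = s1[g] / s0[g];
    U += x[i] - m1;
    I += s2[g] / s0[g] - m1 * m1;
    ll += (b * x[i] - shift) - std::log(s0[g]);
  }
}

// Newton-Raphson univariate Cox fits for every column of X.
// Returns a p x 6 matrix: b, se, z, converged, n_iter, degenerate.
// fast = true performs a single evaluation at b = 0 and reports the score
// statistic z = U/sqrt(I) with the one-step estimate b = U/I.
// [[Rcpp::export]]
NumericMatrix cpp_cox_scan(NumericMatrix X, IntegerVector status,
                           IntegerVector group_start, int max_iter,
                           double tol, double b_cap, bool fast) {
  const int n = X.nrow(), p = X.ncol();
  const int* st = status.begin();
  const int* gs = group_start.begin();
  NumericMatrix out(p, 6);
  std::vector<double> buf(3 * (n + 1));
  double* s0 = buf.data();
  double* s1 = s0 + (n + 1);
  double* s2 = s1 + (n + 1);
  for (int g = 0; g < p; ++g) {
    const double* x = &X(0, g);
    double xmin = x[0], xmax = x[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
    }
    if (!(xmax - xmin > 1e-12)) {            // constant covariate
      out(g, 0) = 0.0; out(g, 1) = NA_REAL; out(g, 2) = 0.0;
      out(g, 3) = 0.0; out(g, 4) = 0.0; out(g, 5) = 1.0;
      continue;
    }
    double U, I, ll;
    if (fast) {
      cox_uvs(x, st, gs, n, 0.0, U, I, ll, s0, s1, s2);
      if (I > 0) {
        out(g, 0) = U / I; out(g, 1) = 1.0 / std::sqrt(I);
        out(g, 2) = U / std::sqrt(I); out(g, 3) = 1.0; out(g, 4) = 1.0;
      } else {
        out(g, 0) = 0.0; out(g, 1) = NA_REAL; out(g, 2) = 0.0;
        out(g, 3) = 0.0; out(g, 4) = 1.0; out(g, 5) = 1.0;
      }
      continue;
    }
    double b = 0.0;
    bool conv = false;
    int it = 0;
    cox_uvs(x, st, gs, n, b, U, I, ll, s0, s1, s2);
    while (it < max_iter) {
      if (std::fabs(U) < tol) { conv = true; break; }
      if (I <= 0) break;
      double step = U / I;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      double bnew = b + step, Un, In, lln;
      cox_uvs(x, st, gs, n, bnew, Un, In, lln, s0, s1, s2);
      int halv = 0;
      while (lln < ll - 1e-12 && halv < 20) {  // step-halving guard
        step *= 0.5; bnew = b + step;
        cox_uvs(x, st, gs, n, bnew, Un, In, lln, s0, s1, s2);
        ++halv;
      }
      b = bnew; U = Un; I = In; ll = lln;
      ++it;
      if (std::fabs(b) > b_cap) break;         // divergence guard
    }
    if (std::fabs(b) > b_cap) conv = false;
    out(g, 0) = b;
    out(g, 1) = (I > 0) ? 1.0 / std::sqrt(I) : NA_REAL;
    out(g, 2) = (I > 0) ? b * std::sqrt(I) : 0.0;
    out(g, 3) = conv ? 1.0 : 0.0;
    out(g, 4) = it;
    out(g, 5) = 0.0;
  }
  return out;
}

// Componentwise-linear boosting of the Cox partial log-likelihood.
// At each step: eta-gradient g_i = delta_i - exp(eta_i) * sum over events j
// with t_j <= t_i of 1/S0_j; univariate least-squares fit of every column to
// the gradient; update eta along the column with the largest RSS reduction,
// scaled by nu. One exp/suffix pass per step serves gradient and
// log-likelihood alike. Returns the final predictor, accumulated
// coefficients, the log-likelihood after every step, and the selected
// column per step.
// [[Rcpp::export]]
List cpp_boost_cox(NumericMatrix X, IntegerVector status,
                   IntegerVector group_start, NumericVector offset,
                   int n_steps, double nu) {
  const int n = X.nrow(), m = X.ncol();
  const int* st = status.begin();
  const int* gsv = group_start.begin();
  NumericVector eta = clone(offset);
  NumericVector coef(m);
  NumericVector llpath(n_steps);
  IntegerVector selected(n_steps, NA_INTEGER);
  std::vector<double> xss(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xss[j] = s;
  }
  std::vector<double> s0(n + 1), w(n), grad(n);

  // one pass over eta: suffix sums, gradient and log-likelihood
  double ll_cur = 0.0;
  auto refresh = [&]() {
    double shift = R_NegInf;
    for (int i = 0; i < n; ++i) if (eta[i] > shift) shift = eta[i];
    if (!R_FINITE(shift)) shift = 0.0;
    s0[n] = 0.0;
    for (int i = n - 1; i >= 0; --i) {
      w[i] = std::exp(eta[i] - shift);
      s0[i] = s0[i + 1] + w[i];
    }
    double ll = 0.0, acc = 0.0;
    int i = 0;
    while (i < n) {
      int gs = gsv[i];
      int gend = i;
      while (gend < n && gsv[gend] == gs) ++gend;
      int nev = 0;
      for (int k = gs; k < gend; ++k)
        if (st[k] == 1) { ++nev; ll += (eta[k] - shift) - std::log(s0[gs]); }
      acc += nev / s0[gs];                    // shift cancels against w
      for (int k = gs; k < gend; ++k) grad[k] = st[k] - w[k] * acc;
      i = gend;
    }
    ll_cur = ll;
  };

  refresh();
  double ll0 = ll_cur;
  for (int step = 0; step < n_steps; ++step) {
    int best = -1;
    double best_score = 0.0, best_b = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xss[j] <= 1e-300) continue;
      const double* xj = &X(0, j);
      double cb = 0.0;
      for (int k = 0; k < n; ++k) cb += xj[k] * grad[k];
      double score = cb * cb / xss[j];        // RSS reduction of column j
      if (score > best_score) { best_score = score; best = j; best_b = cb / xss[j]; }
    }
    if (best >= 0) {
      const double* xb = &X(0, best);
      for (int k = 0; k < n; ++k) eta[k] += nu * best_b * xb[k];
      coef[best] += nu * best_b;
      selected[step] = best + 1;
      refresh();
    }
    llpath[step] = ll_cur;
  }
  return List::create(_["eta"] = eta, _["coef"] = coef,
                      _["loglik_path"] = llpath, _["selected"] = selected,
                      _["loglik0"] = ll0);
}
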