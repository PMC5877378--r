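#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Empirical mode decomposition by sifting.
//
// Envelopes are natural cubic splines through local extrema, with the first
// two extrema mirrored across each boundary before spline fitting so the
// envelope is defined over the whole support. Sifting stops when the
// envelope-mean, normalized by the envelope half-amplitude, is below `tol`
// at >= 95% of samples (hard cap `max_sift` iterations). Decomposition
// stops when the residue has fewer than 4 extrema or `max_imf` is reached.

static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& mx, std::vector<int>& mn) {
  mx.clear(); mn.clear();
  const int n = (int)x.size();
  int i = 1;
  while (i < n - 1) {
    if (x[i] == x[i - 1]) { ++i; continue; } // plateau: defer to its end
    // locate end of any plateau starting at i
    int j = i;
    while (j < n - 1 && x[j + 1] == x[j]) ++j;
    if (j >= n - 1) break;
    const int mid = (i + j) / 2;
    if (x[i] > x[i - 1] && x[j] > x[j + 1]) mx.push_back(mid);
    else if (x[i] < x[i - 1] && x[j] < x[j + 1]) mn.push_back(mid);
    i = j + 1;
  }
}

// Natural cubic spline through (xk, yk), evaluated at 0..n-1.
static void spline_eval(const std::vector<double>& xk,
                        const std::vector<double>& yk,
                        int n, std::vector<double>& out) {
  const int m = (int)xk.size();
  out.assign(n, 0.0);
  if (m == 2) { // straight line
    const double slope = (yk[1] - yk[0]) / (xk[1] - xk[0]);
    for (int t = 0; t < n; ++t) out[t] = yk[0] + slope * (t - xk[0]);
    return;
  }
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m), b(m - 1), d(m - 1);
  for (int i = 0; i < m - 1; ++i) h[i] = xk[i + 1] - xk[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xk[i + 1] - xk[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; c[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) {
    c[i] = z[i] - mu[i] * c[i + 1];
    b[i] = (yk[i + 1] - yk[i]) / h[i] - h[i] * (c[i + 1] + 2.0 * c[i]) / 3.0;
    d[i] = (c[i + 1] - c[i]) / (3.0 * h[i]);
  }
  int seg = 0;
  for (int t = 0; t < n; ++t) {
    const double xt = (double)t;
    while (seg < m - 2 && xt > xk[seg + 1]) ++seg;
    const double dx = xt - xk[seg];
    out[t] = yk[seg] + dx * (b[seg] + dx * (c[seg] + dx * d[seg]));
  }
}

// Mirror up to two extrema across each boundary; clamp with the endpoint
// when it lies outside the first/last extremum's value.
static void extend_knots(const std::vector<int>& idx,
                         const std::vector<double>& x, int n, bool upper,
                         std::vector<double>& xk, std::vector<double>& yk) {
  xk.clear(); yk.clear();
  const int m = (int)idx.size();
  const int nref = std::min(2, m);
  for (int k = nref - 1; k >= 0; --k) {
    if (idx[k] > 0) { xk.push_back(-(double)idx[k]); yk.push_back(x[idx[k]]); }
  }
  // endpoint acts as an extremum if it dominates the first real one
  const bool end0 = upper ? (x[0] >= x[idx[0]]) : (x[0] <= x[idx[0]]);
  if (end0 && idx[0] > 0) { xk.push_back(0.0); yk.push_back(x[0]); }
  for (int k = 0; k < m; ++k) { xk.push_back((double)idx[k]); yk.push_back(x[idx[k]]); }
  const bool endN = upper ? (x[n - 1] >= x[idx[m - 1]]) : (x[n - 1] <= x[idx[m - 1]]);
  if (endN && idx[m - 1] < n - 1) { xk.push_back((double)(n - 1)); yk.push_back(x[n - 1]); }
  for (int k = m - 1; k >= m - nref; --k) {
    if (idx[k] < n - 1) {
      xk.push_back(2.0 * (n - 1) - (double)idx[k]);
      yk.push_back(x[idx[k]]);
    }
  }
}

// One sifting pass chain: refine `work` in place into an IMF.
// Returns the number of sifts performed, or 0 if no envelope was possible.
static int sift_imf(std::vector<double>& work, double tol, int max_sift) {
  const int n = (int)work.size();
  std::vector<int> mx, mn;
  std::vector<double> xku, yku, xkl, ykl, up(n), lo(n);
  int sifts = 0;
  for (int it = 0; it < max_sift; ++it) {
    find_extrema(work, mx, mn);
    if ((int)mx.size() + (int)mn.size() < 4 || mx.empty() || mn.empty())
      return sifts;
    extend_knots(mx, work, n, true, xku, yku);
    extend_knots(mn, work, n, false, xkl, ykl);
    spline_eval(xku, yku, n, up);
    spline_eval(xkl, ykl, n, lo);
    int bad = 0;
    for (int t = 0; t < n; ++t) {
      const double m = 0.5 * (up[t] + lo[t]);
      const double a = 0.5 * (up[t] - lo[t]);
      if (std::fabs(m) > tol * std::max(a, 1e-300)) ++bad;
      work[t] -= m;
    }
    ++sifts;
    if ((double)bad / n <= 0.05) break;
  }
  return sifts;
}

static int count_extrema(const std::vector<double>& x) {
  std::vector<int> mx, mn;
  find_extrema(x, mx, mn);
  return (int)mx.size() + (int)mn.size();
}

// [[Rcpp::export]]
List emd_cpp(NumericVector x, int max_imf = 8, double tol = 0.05,
             int max_sift = 100) {
  const int n = x.size();
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("non-finite value in input signal");
  std::vector<double> res(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> nsift;
  for (int k = 0; k < max_imf; ++k) {
    if (count_extrema(res) < 4) break;
    std::vector<double> work(res);
    const int s = sift_imf(work, tol, max_sift);
    if (s == 0) break;
    imfs.push_back(work);
    nsift.push_back(s);
    for (int t = 0; t < n; ++t) res[t] -= work[t];
  }
  NumericMatrix M(n, (int)imfs.size());
  for (int k = 0; k < (int)imfs.size(); ++k)
    std::copy(imfs[k].begin(), imfs[k].end(), M.column(k).begin());
  return List::create(_["imfs"] = M,
                      _["residue"] = NumericVector(res.begin(), res.end()),
                      _["n_sifts"] = IntegerVector(nsift.begin(), nsift.end()));
}

// Mean absolute first difference of IMF1, one value per column of `X`.
// Columns with no extractable IMF (monotone, < 4 extrema) get the D_t of
// the raw column, matching the convention that such a signal is its own
// fastest component.
// [[Rcpp::export]]
NumericVector imf1_dt_batch(NumericMatrix X, double tol = 0.05,
                            int max_sift = 100) {
  const int n = X.nrow(), m = X.ncol();
  if (n < 2) stop("signals must have at least 2 samples");
  NumericVector out(m);
  std::vector<double> work(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      work[i] = X(i, j);
      if (!R_finite(work[i])) stop("non-finite value in input signal");
    }
    if (count_extrema(work) >= 4) sift_imf(work, tol, max_sift);
    double s = 0.0;
    for (int i = 1; i < n; ++i) s += std::fabs(work[i] - work[i - 1]);
    out[j] = s / (n - 1);
  }
  return out;
}
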