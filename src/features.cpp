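#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Lempel-Ziv 1976 production (exhaustive-history) complexity of a binary
// sequence, counted with the Kaspar-Schuster scanning algorithm.
static int lz76_count_one(const int *s, int n) {
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      k++;
      if (l + k > n) {
        c++;
        break;
      }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == l) {
        c++;
        l += k_max;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  return lz76_count_one(INTEGER(s), s.size());
}

// [[Rcpp::export(name = ".lz76_norm_rows")]]
NumericVector lz76_norm_rows(NumericMatrix w) {
  int n = w.nrow(), m = w.ncol();
  NumericVector out(n);
  std::vector<double> row(m);
  std::vector<int> s(m);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < m; j++) row[j] = w(i, j);
    std::vector<double> tmp(row);
    std::sort(tmp.begin(), tmp.end());
    double med = (m % 2 == 1) ? tmp[m / 2]
                              : 0.5 * (tmp[m / 2 - 1] + tmp[m / 2]);
    for (int j = 0; j < m; j++) s[j] = row[j] >= med ? 1 : 0;
    int c = lz76_count_one(s.data(), m);
    out[i] = c * std::log2((double)m) / m;
  }
  return out;
}

// Correlation sums for the Grassberger-Procaccia estimator: delay-embed
// one window, compute all pairwise distances, and evaluate C(r) on a
// log-spaced radius grid between the 5th and 95th percentiles of the
// positive distances. Returns radii and C(r); degenerate windows give
// zero-length output.
static void d2_curve_one(const double *x, int n, int m, int tau, int nr,
                         std::vector<double> &radii,
                         std::vector<double> &cr) {
  radii.clear();
  cr.clear();
  int np = n - (m - 1) * tau;  // number of embedded points
  if (np < 10) return;
  long npairs = (long)np * (np - 1) / 2;
  std::vector<double> d;
  d.reserve(npairs);
  for (int i = 0; i < np; i++) {
    for (int j = i + 1; j < np; j++) {
      double s = 0.0;
      for (int k = 0; k < m; k++) {
        double diff = x[i + k * tau] - x[j + k * tau];
        s += diff * diff;
      }
      d.push_back(std::sqrt(s));
    }
  }
  std::sort(d.begin(), d.end());
  // drop zero distances for the radius grid
  size_t first_pos = 0;
  while (first_pos < d.size() && d[first_pos] <= 0.0) first_pos++;
  size_t npos = d.size() - first_pos;
  if (npos < 100) return;
  // type-7 quantiles of the positive distances
  auto q7 = [&](double p) {
    double h = p * (npos - 1);
    size_t lo = (size_t)std::floor(h);
    double g = h - lo;
    double a = d[first_pos + lo];
    double b = d[first_pos + std::min(lo + 1, npos - 1)];
    return a + g * (b - a);
  };
  double rlo = q7(0.05), rhi = q7(0.95);
  if (!(rhi > rlo) || rlo <= 0.0) return;
  double llo = std::log(rlo), lhi = std::log(rhi);
  for (int t = 0; t < nr; t++) {
    double r = std::exp(llo + (lhi - llo) * t / (nr - 1));
    // count distances < r via binary search over all pairs
    size_t cnt = std::lower_bound(d.begin(), d.end(), r) - d.begin();
    radii.push_back(r);
    cr.push_back((double)cnt / (double)d.size());
  }
}

// Scaling-region slope: local slopes between consecutive grid points of
// log C vs log r; the widest contiguous segment (>= min_pts radii) whose
// local slopes all lie within `tol` of the segment mean is selected and
// the least-squares slope over it returned. NA when no region exists.
static double d2_estimate_from_curve(const std::vector<double> &radii,
                                     const std::vector<double> &cr,
                                     double tol, int min_pts) {
  std::vector<double> lr, lc;
  for (size_t i = 0; i < radii.size(); i++) {
    if (cr[i] > 0) {
      lr.push_back(std::log(radii[i]));
      lc.push_back(std::log(cr[i]));
    }
  }
  int m = lr.size();
  if (m < min_pts) return NA_REAL;
  std::vector<double> sl(m - 1);
  for (int i = 0; i + 1 < m; i++)
    sl[i] = (lc[i + 1] - lc[i]) / (lr[i + 1] - lr[i]);
  int best_i = -1, best_len = 0;
  for (int i = 0; i + 1 < m; i++) {
    for (int j = i + min_pts - 2; j + 1 < m; j++) {
      // segment of radii i..j+1 uses slopes i..j
      double mean = 0.0;
      for (int t = i; t <= j; t++) mean += sl[t];
      mean /= (j - i + 1);
      bool ok = true;
      for (int t = i; t <= j; t++)
        if (std::fabs(sl[t] - mean) > tol) { ok = false; break; }
      if (ok && (j - i + 2) > best_len) {
        best_len = j - i + 2;
        best_i = i;
      }
    }
  }
  if (best_i < 0) return NA_REAL;
  // least-squares slope over the selected radii
  int a = best_i, b = best_i + best_len - 1;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int nn = b - a + 1;
  for (int t = a; t <= b; t++) {
    sx += lr[t]; sy += lc[t];
    sxx += lr[t] * lr[t]; sxy += lr[t] * lc[t];
  }
  double denom = nn * sxx - sx * sx;
  if (denom <= 0) return NA_REAL;
  return (nn * sxy - sx * sy) / denom;
}

// [[Rcpp::export(name = ".d2_curve")]]
List d2_curve(NumericVector x, int m, int tau, int nr) {
  std::vector<double> radii, cr;
  d2_curve_one(REAL(x), x.size(), m, tau, nr, radii, cr);
  return List::create(_["r"] = wrap(radii), _["C"] = wrap(cr));
}

// [[Rcpp::export(name = ".d2_rows")]]
NumericVector d2_rows(NumericMatrix w, int m, int tau, int nr, double tol,
                      int min_pts) {
  int n = w.nrow(), len = w.ncol();
  NumericVector out(n);
  std::vector<double> row(len), radii, cr;
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < len; j++) row[j] = w(i, j);
    d2_curve_one(row.data(), len, m, tau, nr, radii, cr);
    out[i] = radii.empty() ? NA_REAL
                           : d2_estimate_from_curve(radii, cr, tol, min_pts);
  }
  return out;
}

// Row-wise type-7 quantiles (used for the percentile features).
// [[Rcpp::export(name = ".row_quantiles")]]
NumericMatrix row_quantiles(NumericMatrix w, NumericVector probs) {
  int n = w.nrow(), m = w.ncol(), np = probs.size();
  NumericMatrix out(n, np);
  std::vector<double> row(m);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < m; j++) row[j] = w(i, j);
    std::sort(row.begin(), row.end());
    for (int p = 0; p < np; p++) {
      double h = probs[p] * (m - 1);
      int lo = (int)std::floor(h);
      double g = h - lo;
      int hi = std::min(lo + 1, m - 1);
      out(i, p) = row[lo] + g * (row[hi] - row[lo]);
    }
  }
  return out;
}
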