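#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Brute-force k nearest neighbours with early abandonment on the running
// partial distance. Inputs are feature-major (d x n) so each point is
// contiguous in memory. Distance ties at the k-th neighbour keep the
// earlier training row (stable row order). Returns 1-based neighbour
// indices and their distances, both n_test x k, ordered nearest first.
// metric: 0 = Manhattan, 1 = squared Euclidean (monotone in Euclidean).
// [[Rcpp::export(name = ".knn_kneighbors")]]
List knn_kneighbors(NumericMatrix train_t, NumericMatrix test_t, int k,
                    int metric) {
  int d = train_t.nrow(), n = train_t.ncol(), m = test_t.ncol();
  if (k > n) stop("k exceeds the number of training rows");
  const double *tr = REAL(train_t);
  const double *te = REAL(test_t);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int q = 0; q < m; q++) {
    const double *tq = te + (size_t)q * d;
    int filled = 0;
    double bound = R_PosInf;
    for (int j = 0; j < n; j++) {
      const double *tj = tr + (size_t)j * d;
      // partial distance in chunks: the chunk bodies have no branches,
      // so they vectorize; the abandonment check runs between chunks
      double s = 0.0;
      int r = 0;
      while (r < d) {
        int rend = r + 16 < d ? r + 16 : d;
        if (metric == 0) {
          for (; r < rend; r++) s += std::fabs(tq[r] - tj[r]);
        } else {
          for (; r < rend; r++) {
            double diff = tq[r] - tj[r];
            s += diff * diff;
          }
        }
        if (s > bound) break;
      }
      if (s > bound || (filled == k && s >= bound)) continue;
      // insert (s, j); strict < keeps earlier rows on distance ties
      int pos = filled < k ? filled : k - 1;
      while (pos > 0 && bd[pos - 1] > s) {
        bd[pos] = bd[pos - 1];
        bi[pos] = bi[pos - 1];
        pos--;
      }
      bd[pos] = s;
      bi[pos] = j;
      if (filled < k) filled++;
      if (filled == k) bound = bd[k - 1];
    }
    for (int t = 0; t < k; t++) {
      idx(q, t) = bi[t] + 1;
      dist(q, t) = metric == 0 ? bd[t] : std::sqrt(bd[t]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
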