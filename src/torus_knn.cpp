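// k-nearest-neighbour distances on a flat torus under the l-infinity
// product metric with per-dimension wrapped (circular) distance — the ball
// geometry used by the nearest-neighbour entropy estimator for torsion
// angles. 1-D uses a sorted sweep (O(n k)); higher dimensions use brute
// force with a per-point max-heap (O(n^2 d), adequate for the subsample
// sizes the estimator uses).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// inputs are wrapped to (-pi, pi], so |a - b| < 2 pi always
static inline double wdist(double a, double b) {
  double d = std::fabs(a - b);
  return d > M_PI ? 2.0 * M_PI - d : d;
}

// [[Rcpp::export]]
NumericVector torus_knn_dist(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k < 1) stop("k must be >= 1");
  if (k >= n) stop("k must be smaller than the sample size");
  NumericVector out(n);
  if (d == 1) {
    std::vector<std::pair<double, int> > v(n);
    for (int i = 0; i < n; ++i) v[i] = std::make_pair(x(i, 0), i);
    std::sort(v.begin(), v.end());
    std::vector<double> cand(2 * k);
    for (int i = 0; i < n; ++i) {
      for (int j = 1; j <= k; ++j) {
        int r = i + j; if (r >= n) r -= n;
        int l = i - j; if (l < 0) l += n;
        cand[2 * (j - 1)] = wdist(v[i].first, v[r].first);
        cand[2 * (j - 1) + 1] = wdist(v[i].first, v[l].first);
      }
      std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
      out[v[i].second] = cand[k - 1];
    }
  } else {
    std::vector<double> heap(k);
    for (int i = 0; i < n; ++i) {
      int filled = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dist = 0.0;
        for (int c = 0; c < d; ++c) {
          double w = wdist(x(i, c), x(j, c));
          if (w > dist) dist = w;
        }
        if (filled < k) {
          heap[filled++] = dist;
          if (filled == k) std::make_heap(heap.begin(), heap.end());
        } else if (dist < heap.front()) {
          std::pop_heap(heap.begin(), heap.end());
          heap[k - 1] = dist;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      out[i] = heap.front();
    }
  }
  return out;
}
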