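#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Marker-seeded compact watershed on an edge-strength image.
// Seeds flood outward through a priority queue; a pixel's cost is the edge
// strength at the pixel plus compactness times its squared Euclidean
// distance to the seed, which keeps regions compact even across flat edge
// images. Ties resolve by insertion order (FIFO), so the labelling is
// deterministic. 4-connectivity.
struct QItem {
  double cost;
  unsigned long order;
  int idx;
  int label;
  int seed_r, seed_c;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.order > b.order;
  }
};

// [[Rcpp::export(name = ".compact_watershed_cpp")]]
IntegerMatrix compact_watershed_cpp(NumericMatrix edges,
                                    IntegerMatrix seeds,
                                    double compactness) {
  int nr = edges.nrow(), nc = edges.ncol();
  IntegerMatrix labels(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long order = 0;
  for (int k = 0; k < seeds.nrow(); ++k) {
    int r = seeds(k, 0) - 1, c = seeds(k, 1) - 1;
    QItem it {0.0, order++, r + c * nr, k + 1, r, c};
    pq.push(it);
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int r = it.idx % nr, c = it.idx / nr;
    if (labels(r, c) != 0) continue;
    labels(r, c) = it.label;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) != 0) continue;
      double dist2 = (double)(rr - it.seed_r) * (rr - it.seed_r) +
                     (double)(cc - it.seed_c) * (cc - it.seed_c);
      QItem nx {edges(rr, cc) + compactness * dist2, order++,
                rr + cc * nr, it.label, it.seed_r, it.seed_c};
      pq.push(nx);
    }
  }
  return labels;
}

// Joint spatial/range mean-shift filtering of a multi-band image.
// For each pixel, iteratively replaces its band vector with the mean of
// neighbours within `spatial` pixels whose band vector lies within `range`
// (Euclidean) of the current estimate, until convergence or max_iter.
// [[Rcpp::export(name = ".meanshift_filter_cpp")]]
NumericVector meanshift_filter_cpp(NumericVector img, int nr, int nc, int nb,
                                   int spatial, double range, int max_iter) {
  NumericVector out(img.size());
  std::vector<double> cur(nb), acc(nb);
  double range2 = range * range;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int b = 0; b < nb; ++b) cur[b] = img[r + c * nr + b * nr * nc];
      for (int iter = 0; iter < max_iter; ++iter) {
        std::fill(acc.begin(), acc.end(), 0.0);
        int n = 0;
        int r0 = std::max(0, r - spatial), r1 = std::min(nr - 1, r + spatial);
        int c0 = std::max(0, c - spatial), c1 = std::min(nc - 1, c + spatial);
        for (int cc = c0; cc <= c1; ++cc) {
          for (int rr = r0; rr <= r1; ++rr) {
            double d2 = 0;
            for (int b = 0; b < nb; ++b) {
              double diff = img[rr + cc * nr + b * nr * nc] - cur[b];
              d2 += diff * diff;
              if (d2 > range2) break;
            }
            if (d2 <= range2) {
              for (int b = 0; b < nb; ++b)
                acc[b] += img[rr + cc * nr + b * nr * nc];
              ++n;
            }
          }
        }
        double shift = 0;
        for (int b = 0; b < nb; ++b) {
          double m = acc[b] / n;
          shift += (m - cur[b]) * (m - cur[b]);
          cur[b] = m;
        }
        if (shift < 1e-10) break;
      }
      for (int b = 0; b < nb; ++b) out[r + c * nr + b * nr * nc] = cur[b];
    }
  }
  return out;
}
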