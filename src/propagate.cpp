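// Best-first expansion of the seeded path-connectivity likelihood over the
// 6-connected voxel lattice. Each voxel is finalized once, at the moment it is
// popped with the highest current likelihood (ties broken by lexicographic
// linear index); until finalization it may be re-relaxed by better offers.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
struct QEntry {
  double lik;
  int idx;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.lik != b.lik) return a.lik < b.lik;  // max-heap on likelihood
    return a.idx > b.idx;                      // then smallest index first
  }
};
}  // namespace

// intens: voxel intensities (column-major, dim d); seeds: 0-based linear seed
// indices; iw: per-voxel intensity weight (length 1 => constant); spacing in
// mm per axis; delta_dis: seed path-distance offset (mm).
// [[Rcpp::export(name = ".propagate_cpp")]]
NumericVector propagate_cpp(NumericVector intens, IntegerVector dim,
                            IntegerVector seeds, NumericVector iw,
                            NumericVector spacing, double mu,
                            double delta_dis, double eps_floor) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (intens.size() != n) stop("intensity/dim mismatch");
  const bool const_iw = (iw.size() == 1);
  std::vector<double> lik(n, 0.0), ibar(n, 0.0), dis(n, 0.0);
  std::vector<char> final_(n, 0), is_seed(n, 0);

  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  for (R_xlen_t k = 0; k < seeds.size(); ++k) {
    int s = seeds[k];
    if (s < 0 || s >= n) stop("seed index out of range");
    is_seed[s] = 1;
    lik[s] = 1.0;
    ibar[s] = intens[s];
    dis[s] = delta_dis;
    pq.push({1.0, s});
  }
  if (seeds.size() == 0) stop("empty seed set");

  const int off1 = 1, off2 = d1, off3 = d1 * d2;
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    const int v = e.idx;
    if (final_[v] || e.lik != lik[v]) continue;
    final_[v] = 1;
    const int i1 = v % d1, i2 = (v / d1) % d2, i3 = v / (d1 * d2);
    for (int ax = 0; ax < 3; ++ax) {
      const int lo = (ax == 0) ? i1 : (ax == 1) ? i2 : i3;
      const int hi = (ax == 0) ? d1 : (ax == 1) ? d2 : d3;
      const int off = (ax == 0) ? off1 : (ax == 1) ? off2 : off3;
      const double step = spacing[ax];
      for (int s = -1; s <= 1; s += 2) {
        if ((s < 0 && lo == 0) || (s > 0 && lo == hi - 1)) continue;
        const int w = v + s * off;
        if (final_[w] || is_seed[w]) continue;
        const double di = intens[w] - ibar[v];
        const double wgt = const_iw ? iw[0] : iw[w];
        const double denom = step + dis[v];
        // path strength: the path's weakest step (fuzzy-connectivity
        // composition); best-first finalization then yields the exact
        // maximum over all paths
        double cand = std::min(lik[v],
                               std::exp(-wgt * mu * di * di / denom));
        if (cand > lik[w]) {
          lik[w] = cand;
          ibar[w] = 0.5 * (intens[w] + ibar[v]);
          dis[w] = step + dis[v];
          pq.push({cand, w});
        }
      }
    }
  }

  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    double L = lik[k];
    if (L < eps_floor) L = eps_floor;
    if (L > 1.0) L = 1.0;
    out[k] = L;
  }
  out.attr("dim") = dim;
  return out;
}
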