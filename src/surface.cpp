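// Symmetric surface distances between two binary masks.
// Border voxels are mask voxels with at least one 6-neighbor outside the mask
// (the array boundary counts as background). Distances are voxel-center
// Euclidean distances in mm.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
void border_voxels(const LogicalVector& mask, const IntegerVector& dim,
                   std::vector<double>& x, std::vector<double>& y,
                   std::vector<double>& z, const NumericVector& sp) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int off[3] = {1, d1, d1 * d2};
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t v = i + (R_xlen_t)d1 * j + (R_xlen_t)d1 * d2 * k;
        if (!mask[v]) continue;
        bool border = (i == 0 || i == d1 - 1 || j == 0 || j == d2 - 1 ||
                       k == 0 || k == d3 - 1);
        if (!border) {
          border = !mask[v - off[0]] || !mask[v + off[0]] ||
                   !mask[v - off[1]] || !mask[v + off[1]] ||
                   !mask[v - off[2]] || !mask[v + off[2]];
        }
        if (border) {
          x.push_back(i * sp[0]);
          y.push_back(j * sp[1]);
          z.push_back(k * sp[2]);
        }
      }
}

void min_dists(const std::vector<double>& ax, const std::vector<double>& ay,
               const std::vector<double>& az, const std::vector<double>& bx,
               const std::vector<double>& by, const std::vector<double>& bz,
               std::vector<double>& out) {
  for (size_t i = 0; i < ax.size(); ++i) {
    double best = R_PosInf;
    for (size_t j = 0; j < bx.size(); ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j], dz = az[i] - bz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out.push_back(std::sqrt(best));
  }
}
}  // namespace

// Returns all symmetric border-to-surface distances (A->B then B->A).
// [[Rcpp::export(name = ".surface_dists_cpp")]]
NumericVector surface_dists_cpp(LogicalVector a, LogicalVector b,
                                IntegerVector dim, NumericVector spacing) {
  std::vector<double> ax, ay, az, bx, by, bz;
  border_voxels(a, dim, ax, ay, az, spacing);
  border_voxels(b, dim, bx, by, bz, spacing);
  if (ax.empty() || bx.empty()) stop("empty mask has no surface");
  std::vector<double> d;
  d.reserve(ax.size() + bx.size());
  min_dists(ax, ay, az, bx, by, bz, d);
  min_dists(bx, by, bz, ax, ay, az, d);
  return NumericVector(d.begin(), d.end());
}
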