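#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Mean distance to the nearest other point, averaged over all points.
// Uniform grid with expanding-shell search; exact.
// [[Rcpp::export]]
double cpp_mean_nn_distance(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  double xmin[3], xmax[3];
  for (int d = 0; d < 3; ++d) { xmin[d] = R_PosInf; xmax[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (v < xmin[d]) xmin[d] = v;
      if (v > xmax[d]) xmax[d] = v;
    }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(xmax[d] - xmin[d], 1e-9);
  // cell size ~ expected nn distance
  double cell = 1.5 * std::cbrt(vol / n);
  if (!(cell > 0)) cell = 1.0;
  int dims[3];
  for (int d = 0; d < 3; ++d) {
    dims[d] = std::max(1, (int)std::floor((xmax[d] - xmin[d]) / cell) + 1);
  }
  auto cellIndex = [&](int ix, int iy, int iz) -> long long {
    return ((long long)iz * dims[1] + iy) * dims[0] + ix;
  };
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(dims[0] - 1, (int)((pts(i, 0) - xmin[0]) / cell));
    int iy = std::min(dims[1] - 1, (int)((pts(i, 1) - xmin[1]) / cell));
    int iz = std::min(dims[2] - 1, (int)((pts(i, 2) - xmin[2]) / cell));
    ci[i] = ix; cj[i] = iy; ck[i] = iz;
    grid[cellIndex(ix, iy, iz)].push_back(i);
  }
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int maxshell = std::max(dims[0], std::max(dims[1], dims[2]));
    for (int shell = 0; shell <= maxshell; ++shell) {
      // once a neighbour is found, we must still scan one extra shell ring
      // to guarantee exactness, then stop
      if (std::isfinite(best) && (double)(shell - 1) * cell > std::sqrt(best))
        break;
      bool any = false;
      for (int dx = -shell; dx <= shell; ++dx) {
        int ix = ci[i] + dx;
        if (ix < 0 || ix >= dims[0]) continue;
        for (int dy = -shell; dy <= shell; ++dy) {
          int iy = cj[i] + dy;
          if (iy < 0 || iy >= dims[1]) continue;
          for (int dz = -shell; dz <= shell; ++dz) {
            // only the surface of the shell
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != shell)
              continue;
            int iz = ck[i] + dz;
            if (iz < 0 || iz >= dims[2]) continue;
            any = true;
            auto it = grid.find(cellIndex(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double d2 = 0;
              for (int d = 0; d < 3; ++d) {
                double diff = pts(i, d) - pts(j, d);
                d2 += diff * diff;
              }
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (!any && shell > 0 && std::isfinite(best)) break;
    }
    total += std::sqrt(best);
  }
  return total / n;
}
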