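#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// minimum distance between 3D segments p1-q1 and p2-q2 (Ericson, RTCD 5.1.9)
static double seg_seg_dist2(const double* p1, const double* q1,
                            const double* p2, const double* q2) {
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = q1[i] - p1[i];
    d2[i] = q2[i] - p2[i];
    r[i] = p1[i] - p2[i];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double dd = 0.0;
  for (int i = 0; i < 3; ++i) {
    double ci = (p1[i] + s * d1[i]) - (p2[i] + t * d2[i]);
    dd += ci * ci;
  }
  return dd;
}

// [[Rcpp::export]]
double cpp_segment_distance(NumericVector p1, NumericVector q1,
                            NumericVector p2, NumericVector q2) {
  return std::sqrt(seg_seg_dist2(&p1[0], &q1[0], &p2[0], &q2[0]));
}

static void fill_seg(const NumericMatrix& m, int i, double* p, double* q) {
  p[0] = m(i, 0); p[1] = m(i, 1); p[2] = m(i, 2);
  q[0] = m(i, 3); q[1] = m(i, 4); q[2] = m(i, 5);
}

// Axo-dendritic apposition detection. src: axon segments (x1,y1,z1,x2,y2,z2),
// src_cell: 1-based cell id per segment; tgt/tgt_cell likewise for dendrite
// segments. An apposition is a source segment within `threshold` of any
// dendrite segment of a target cell; each source segment counts at most once
// per target cell. Self pairs (same cell id) are excluded.
// brute = true does the all-pairs scan (oracle); otherwise a uniform spatial
// hash over dendrite segments is used; the two paths return identical edges.
// [[Rcpp::export]]
DataFrame cpp_appositions(NumericMatrix src, IntegerVector src_cell,
                          NumericMatrix tgt, IntegerVector tgt_cell,
                          double threshold, bool brute = false) {
  const int ns = src.nrow(), nt = tgt.nrow();
  const double thr2 = threshold * threshold;
  std::map<std::pair<int,int>, int> counts;
  double p1[3], q1[3], p2[3], q2[3];
  if (brute) {
    for (int i = 0; i < ns; ++i) {
      fill_seg(src, i, p1, q1);
      std::vector<int> hit;
      for (int j = 0; j < nt; ++j) {
        if (src_cell[i] == tgt_cell[j]) continue;
        fill_seg(tgt, j, p2, q2);
        if (seg_seg_dist2(p1, q1, p2, q2) <= thr2) hit.push_back(tgt_cell[j]);
      }
      std::sort(hit.begin(), hit.end());
      hit.erase(std::unique(hit.begin(), hit.end()), hit.end());
      for (int c : hit) counts[std::make_pair(src_cell[i], c)]++;
    }
  } else {
    // uniform hash grid: every dendrite segment is inserted into all cells
    // its bounding box overlaps, so a query only needs the cells overlapped
    // by the source segment's threshold-expanded bounding box (no margin).
    // Cell size balances insertion duplication against candidate count.
    double meanlen = 0.0;
    double xmin[3] = {R_PosInf, R_PosInf, R_PosInf};
    for (int j = 0; j < nt; ++j) {
      fill_seg(tgt, j, p2, q2);
      double l2 = 0;
      for (int d = 0; d < 3; ++d) {
        l2 += (q2[d] - p2[d]) * (q2[d] - p2[d]);
        xmin[d] = std::min(xmin[d], std::min(p2[d], q2[d]));
      }
      meanlen += std::sqrt(l2);
    }
    meanlen /= std::max(1, nt);
    const double cell = std::max(meanlen, 2.0 * threshold) + 1e-9;
    auto key = [&](long long ix, long long iy, long long iz) -> long long {
      return ((ix + 1048576LL) << 42) | ((iy + 1048576LL) << 21) | (iz + 1048576LL);
    };
    std::unordered_map<long long, std::vector<int> > grid;
    grid.reserve(2 * nt);
    for (int j = 0; j < nt; ++j) {
      fill_seg(tgt, j, p2, q2);
      long long c0[3], c1[3];
      for (int d = 0; d < 3; ++d) {
        c0[d] = (long long)std::floor((std::min(p2[d], q2[d]) - xmin[d]) / cell);
        c1[d] = (long long)std::floor((std::max(p2[d], q2[d]) - xmin[d]) / cell);
      }
      for (long long ix = c0[0]; ix <= c1[0]; ++ix)
        for (long long iy = c0[1]; iy <= c1[1]; ++iy)
          for (long long iz = c0[2]; iz <= c1[2]; ++iz)
            grid[key(ix, iy, iz)].push_back(j);
    }
    std::vector<int> stamp(nt, -1);
    std::vector<int> hit;
    for (int i = 0; i < ns; ++i) {
      fill_seg(src, i, p1, q1);
      long long c0[3], c1[3];
      for (int d = 0; d < 3; ++d) {
        c0[d] = (long long)std::floor((std::min(p1[d], q1[d]) - threshold - xmin[d]) / cell);
        c1[d] = (long long)std::floor((std::max(p1[d], q1[d]) + threshold - xmin[d]) / cell);
      }
      hit.clear();
      for (long long ix = c0[0]; ix <= c1[0]; ++ix)
        for (long long iy = c0[1]; iy <= c1[1]; ++iy)
          for (long long iz = c0[2]; iz <= c1[2]; ++iz) {
            auto it = grid.find(key(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (stamp[j] == i) continue;
              stamp[j] = i;
              if (src_cell[i] == tgt_cell[j]) continue;
              fill_seg(tgt, j, p2, q2);
              if (seg_seg_dist2(p1, q1, p2, q2) <= thr2) hit.push_back(tgt_cell[j]);
            }
          }
      std::sort(hit.begin(), hit.end());
      hit.erase(std::unique(hit.begin(), hit.end()), hit.end());
      for (int c : hit) counts[std::make_pair(src_cell[i], c)]++;
    }
  }
  const int ne = counts.size();
  IntegerVector esrc(ne), edst(ne), ecnt(ne);
  int k = 0;
  for (auto& kv : counts) {
    esrc[k] = kv.first.first;
    edst[k] = kv.first.second;
    ecnt[k] = kv.second;
    ++k;
  }
  return DataFrame::create(_["src"] = esrc, _["dst"] = edst,
                           _["appositions"] = ecnt);
}
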