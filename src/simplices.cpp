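#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Directed simplex counting by recursive out-neighbourhood intersection.
// A directed k-simplex is an ordered tuple (v0,...,vk) of distinct vertices
// with an edge vi -> vj for every i < j; each simplex is counted once (the
// ordering is determined by its edges). counts[0] = vertex count,
// counts[1] = edge count.
static void rec_count(const std::vector<std::vector<int> >& adj,
                      const std::vector<int>& cand, int depth,
                      std::vector<double>& counts, int max_dim) {
  if (depth >= (int)counts.size()) counts.resize(depth + 1, 0.0);
  counts[depth] += (double)cand.size();
  if (max_dim >= 0 && depth >= max_dim) return;
  std::vector<int> next;
  for (int u : cand) {
    next.clear();
    std::set_intersection(cand.begin(), cand.end(),
                          adj[u].begin(), adj[u].end(),
                          std::back_inserter(next));
    if (!next.empty()) rec_count(adj, next, depth + 1, counts, max_dim);
  }
}

// edges: 1-based src/dst vectors; n: vertex count; max_dim < 0 means
// unbounded (run to exhaustion).
// [[Rcpp::export]]
NumericVector cpp_count_simplices(int n, IntegerVector src, IntegerVector dst,
                                  int max_dim = -1) {
  std::vector<std::vector<int> > adj(n);
  const int m = src.size();
  for (int e = 0; e < m; ++e) {
    int a = src[e] - 1, b = dst[e] - 1;
    if (a < 0 || a >= n || b < 0 || b >= n) stop("edge endpoint out of range");
    if (a == b) continue;
    adj[a].push_back(b);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<double> counts;
  counts.push_back((double)n);
  if (max_dim != 0) {
    for (int v = 0; v < n; ++v)
      if (!adj[v].empty())
        rec_count(adj, adj[v], 1, counts, max_dim);
  }
  return NumericVector(counts.begin(), counts.end());
}
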