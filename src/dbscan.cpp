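#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// DBSCAN on 3D points. Euclidean distance, eps-neighbourhoods computed by
// plain O(n^2) region queries (n per cell is a few thousand at most).
// Conventions: a core point has >= minpts points within eps *including
// itself*; border points reachable from several clusters go to the
// first-discovered cluster, with points visited in index order, so the
// labelling is deterministic. Labels: 0 = noise, clusters numbered from 1.
// [[Rcpp::export]]
IntegerVector dbscan_labels(NumericMatrix pts, double eps, int minpts) {
  const int n = pts.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  const double eps2 = eps * eps;
  std::vector<bool> visited(n, false);

  std::vector<int> neigh;
  auto region_query = [&](int i, std::vector<int>& out) {
    out.clear();
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz <= eps2) out.push_back(j);
    }
  };

  int cluster = 0;
  std::vector<int> seeds, nb;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    region_query(i, neigh);
    if ((int)neigh.size() < minpts) continue;  // noise unless claimed later
    ++cluster;
    labels[i] = cluster;
    seeds.assign(neigh.begin(), neigh.end());
    for (size_t k = 0; k < seeds.size(); ++k) {
      const int j = seeds[k];
      if (labels[j] == 0) labels[j] = cluster;  // claim noise/unlabelled point
      if (visited[j]) continue;
      visited[j] = true;
      region_query(j, nb);
      if ((int)nb.size() >= minpts) {
        for (int q : nb) {
          if (!visited[q] || labels[q] == 0) seeds.push_back(q);
        }
      }
    }
  }
  return labels;
}
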