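#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Global topology metrics of a binary undirected graph via breadth-first
// search from every node:
//   Lg - characteristic path length, averaged over reachable ordered pairs
//        (the fraction of unreachable pairs is reported alongside);
//   Cg - mean local clustering coefficient, nodes with degree < 2 count 0;
//   Eg - global efficiency, mean of 1/d over ordered pairs (0 for
//        unreachable pairs);
//   El - local efficiency, mean over nodes of the global efficiency of the
//        neighbor-induced subgraph (nodes with < 2 neighbors count 0).
// [[Rcpp::export]]
List graph_metrics_cpp(IntegerMatrix adj) {
  const int n = adj.nrow();
  if (n < 2) stop("graph metrics require at least 2 nodes");
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nb[i].push_back(j);

  // all-pairs BFS for Lg and Eg
  double sum_d = 0.0, sum_inv = 0.0;
  long long reachable = 0;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nb[u]) if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
    for (int t = 0; t < n; ++t) {
      if (t == s) continue;
      if (dist[t] > 0) {
        sum_d += dist[t];
        sum_inv += 1.0 / dist[t];
        ++reachable;
      }
    }
  }
  const double npairs = (double)n * (n - 1);
  double Lg = reachable > 0 ? sum_d / reachable : NA_REAL;
  double Eg = sum_inv / npairs;
  double frac_disc = 1.0 - reachable / npairs;

  // clustering coefficient
  double Cg = 0.0;
  for (int i = 0; i < n; ++i) {
    const int k = nb[i].size();
    if (k < 2) continue;
    int e = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb[i][a], nb[i][b]) != 0) ++e;
    Cg += 2.0 * e / ((double)k * (k - 1));
  }
  Cg /= n;

  // local efficiency: Eg of each neighbor-induced subgraph
  double El = 0.0;
  for (int i = 0; i < n; ++i) {
    const int k = nb[i].size();
    if (k < 2) continue;
    // BFS inside the subgraph induced by nb[i]
    std::vector<int> idx(n, -1);
    for (int a = 0; a < k; ++a) idx[nb[i][a]] = a;
    double sub_inv = 0.0;
    std::vector<int> sd(k);
    for (int a = 0; a < k; ++a) {
      std::fill(sd.begin(), sd.end(), -1);
      sd[a] = 0;
      std::queue<int> q;
      q.push(a);
      while (!q.empty()) {
        int u = q.front(); q.pop();
        for (int v : nb[nb[i][u]]) {
          int w = idx[v];
          if (w >= 0 && sd[w] < 0) { sd[w] = sd[u] + 1; q.push(w); }
        }
      }
      for (int b = 0; b < k; ++b)
        if (b != a && sd[b] > 0) sub_inv += 1.0 / sd[b];
    }
    El += sub_inv / ((double)k * (k - 1));
  }
  El /= n;

  double mean_degree = 0.0;
  for (int i = 0; i < n; ++i) mean_degree += nb[i].size();
  mean_degree /= n;

  return List::create(_["Lg"] = Lg, _["Cg"] = Cg, _["Eg"] = Eg, _["El"] = El,
                      _["mean_degree"] = mean_degree,
                      _["frac_disconnected"] = frac_disc);
}
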