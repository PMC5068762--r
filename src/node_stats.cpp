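#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Per-node statistics of a connected, simple, undirected, unweighted graph
// via one Brandes-style BFS pass per source: degree, stress (number of
// shortest paths through the node), betweenness (normalized by the number
// of endpoint-excluded unordered pairs), eccentricity and mean shortest
// path length.  Edges are 0-based node index pairs.
// [[Rcpp::export(name = ".node_stats_cpp")]]
DataFrame node_stats_cpp(int n, IntegerMatrix edges) {
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0), b = edges(i, 1);
    if (a < 0 || b < 0 || a >= n || b >= n)
      stop("edge index out of range");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }

  std::vector<double> stress(n, 0.0), btw(n, 0.0), avg(n, 0.0);
  std::vector<int> ecc(n, 0), degree(n);
  for (int v = 0; v < n; ++v) degree[v] = (int) adj[v].size();

  std::vector<int> dist(n), order;
  std::vector<double> sigma(n), delta_b(n), delta_s(n);
  std::vector<std::vector<int>> pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta_b.begin(), delta_b.end(), 0.0);
    std::fill(delta_s.begin(), delta_s.end(), 0.0);
    for (int v = 0; v < n; ++v) pred[v].clear();
    order.clear();

    std::queue<int> q;
    dist[s] = 0; sigma[s] = 1.0;
    q.push(s);
    long long dist_sum = 0;
    int dist_max = 0;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      dist_sum += dist[v];
      if (dist[v] > dist_max) dist_max = dist[v];
      for (int w : adj[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    if ((int) order.size() != n)
      stop("graph is disconnected; run on the largest component");

    // reverse BFS order accumulation
    for (int i = n - 1; i >= 1; --i) {
      int w = order[i];
      for (int v : pred[w]) {
        double c = sigma[v] / sigma[w];
        delta_b[v] += c * (1.0 + delta_b[w]);
        delta_s[v] += sigma[v] * (1.0 + delta_s[w] / sigma[w]);
      }
      if (w != s) {
        btw[w] += delta_b[w];
        stress[w] += delta_s[w];
      }
    }
    ecc[s] = dist_max;
    avg[s] = n > 1 ? (double) dist_sum / (n - 1) : 0.0;
  }

  // each unordered pair contributed from both endpoints
  double pairs = n > 2 ? (double) (n - 1) * (n - 2) / 2.0 : 1.0;
  NumericVector stress_out(n), btw_out(n), avg_out(n);
  IntegerVector ecc_out(n), deg_out(n);
  for (int v = 0; v < n; ++v) {
    stress_out[v] = stress[v] / 2.0;
    btw_out[v] = (btw[v] / 2.0) / pairs;
    avg_out[v] = avg[v];
    ecc_out[v] = ecc[v];
    deg_out[v] = degree[v];
  }
  return DataFrame::create(
    _["degree"] = deg_out,
    _["stress"] = stress_out,
    _["betweenness"] = btw_out,
    _["eccentricity"] = ecc_out,
    _["avg_shortest_path"] = avg_out
  );
}
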