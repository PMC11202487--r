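#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Depth-bounded DFS over an adjacency list. Counts simple paths (no
// vertex revisits) of edge-length 1..maxlen starting at `v`. Counts are
// accumulated in double: path counts grow with branching^maxlen and can
// exceed 32-bit range on dense graphs.
static void dfs_count(const std::vector<std::vector<int> >& adj,
                      int v, int depth, int maxlen,
                      std::vector<char>& visited, double& count) {
  if (depth == maxlen) return;
  const std::vector<int>& nb = adj[v];
  for (size_t i = 0; i < nb.size(); ++i) {
    int w = nb[i];
    if (!visited[w]) {
      count += 1.0;
      if (depth + 1 < maxlen) {
        visited[w] = 1;
        dfs_count(adj, w, depth + 1, maxlen, visited, count);
        visited[w] = 0;
      }
    }
  }
}

static std::vector<std::vector<int> > build_adj(const List& adj_list) {
  int n = adj_list.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i].assign(nb.begin(), nb.end());
    for (size_t j = 0; j < adj[i].size(); ++j) {
      if (adj[i][j] < 0 || adj[i][j] >= n)
        stop("adjacency index out of range");
    }
  }
  return adj;
}

// [[Rcpp::export]]
double count_paths_source_cpp(List adj_list, int source, int maxlen) {
  std::vector<std::vector<int> > adj = build_adj(adj_list);
  int n = adj.size();
  if (source < 0 || source >= n) stop("source index out of range");
  if (maxlen < 1) stop("maxlen must be >= 1");
  std::vector<char> visited(n, 0);
  visited[source] = 1;
  double count = 0.0;
  dfs_count(adj, source, 0, maxlen, visited, count);
  return count;
}

// [[Rcpp::export]]
NumericVector count_paths_all_cpp(List adj_list, int maxlen) {
  std::vector<std::vector<int> > adj = build_adj(adj_list);
  int n = adj.size();
  if (maxlen < 1) stop("maxlen must be >= 1");
  NumericVector out(n);
  std::vector<char> visited(n, 0);
  for (int s = 0; s < n; ++s) {
    visited[s] = 1;
    double count = 0.0;
    dfs_count(adj, s, 0, maxlen, visited, count);
    visited[s] = 0;
    out[s] = count;
  }
  return out;
}
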