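#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Strongly connected components over a descending sequence of thresholds.
//
// For threshold delta, the directed graph has edge j -> i iff S(i, j) >= delta
// and i != j (edge direction is irrelevant for SCC membership, but the
// convention is kept explicit). Edges are pre-sorted by weight once and added
// incrementally as the threshold decreases, so the work per threshold is
// O(V + E_at_threshold) for an iterative Tarjan pass.

struct EdgeRec {
  double w;
  int from, to;
};

static void tarjan_scc(int n, const std::vector<std::vector<int> > &adj,
                       std::vector<int> &comp) {
  std::vector<int> index(n, -1), low(n, 0), on_stack(n, 0);
  std::vector<int> stack_v;  // Tarjan stack
  // explicit DFS stack: node and position in its adjacency list
  std::vector<std::pair<int, size_t> > dfs;
  int next_index = 0, next_comp = 0;
  comp.assign(n, -1);
  for (int root = 0; root < n; ++root) {
    if (index[root] != -1) continue;
    dfs.push_back(std::make_pair(root, (size_t)0));
    index[root] = low[root] = next_index++;
    stack_v.push_back(root);
    on_stack[root] = 1;
    while (!dfs.empty()) {
      int v = dfs.back().first;
      size_t &pos = dfs.back().second;
      if (pos < adj[v].size()) {
        int w = adj[v][pos++];
        if (index[w] == -1) {
          index[w] = low[w] = next_index++;
          stack_v.push_back(w);
          on_stack[w] = 1;
          dfs.push_back(std::make_pair(w, (size_t)0));
        } else if (on_stack[w]) {
          if (index[w] < low[v]) low[v] = index[w];
        }
      } else {
        if (low[v] == index[v]) {
          int u;
          do {
            u = stack_v.back();
            stack_v.pop_back();
            on_stack[u] = 0;
            comp[u] = next_comp;
          } while (u != v);
          ++next_comp;
        }
        dfs.pop_back();
        if (!dfs.empty()) {
          int parent = dfs.back().first;
          if (low[v] < low[parent]) low[parent] = low[v];
        }
      }
    }
  }
}

static std::vector<EdgeRec> sorted_edges(const NumericMatrix &S) {
  int n = S.nrow();
  std::vector<EdgeRec> edges;
  edges.reserve((size_t)n * (n - 1));
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      EdgeRec e;
      e.w = S(i, j);
      e.from = j;  // edge j -> i carries weight S(i, j)
      e.to = i;
      edges.push_back(e);
    }
  }
  std::sort(edges.begin(), edges.end(),
            [](const EdgeRec &a, const EdgeRec &b) { return a.w > b.w; });
  return edges;
}

// Canonicalize component labels so each component is named by its smallest
// member index (stable across runs and label orders).
static void canonicalize(std::vector<int> &comp, int n) {
  std::vector<int> first(n, -1);
  for (int v = 0; v < n; ++v)
    if (first[comp[v]] == -1) first[comp[v]] = v;
  for (int v = 0; v < n; ++v) comp[v] = first[comp[v]];
}

// [[Rcpp::export(name = ".scc_memberships")]]
IntegerMatrix scc_memberships(NumericMatrix S, NumericVector thresholds) {
  int n = S.nrow(), T = thresholds.size();
  std::vector<EdgeRec> edges = sorted_edges(S);
  std::vector<std::vector<int> > adj(n);
  IntegerMatrix out(T, n);
  size_t pos = 0;
  std::vector<int> comp;
  for (int t = 0; t < T; ++t) {
    double delta = thresholds[t];
    while (pos < edges.size() && edges[pos].w >= delta) {
      adj[edges[pos].from].push_back(edges[pos].to);
      ++pos;
    }
    tarjan_scc(n, adj, comp);
    canonicalize(comp, n);
    for (int v = 0; v < n; ++v) out(t, v) = comp[v] + 1;  // 1-based labels
  }
  return out;
}

// [[Rcpp::export(name = ".largest_scc_sizes")]]
IntegerVector largest_scc_sizes(NumericMatrix S, NumericVector thresholds) {
  int n = S.nrow(), T = thresholds.size();
  std::vector<EdgeRec> edges = sorted_edges(S);
  std::vector<std::vector<int> > adj(n);
  IntegerVector out(T);
  size_t pos = 0;
  std::vector<int> comp, count;
  for (int t = 0; t < T; ++t) {
    double delta = thresholds[t];
    while (pos < edges.size() && edges[pos].w >= delta) {
      adj[edges[pos].from].push_back(edges[pos].to);
      ++pos;
    }
    tarjan_scc(n, adj, comp);
    count.assign(n, 0);
    int best = 0;
    for (int v = 0; v < n; ++v) {
      int c = ++count[comp[v]];
      if (c > best) best = c;
    }
    out[t] = best;
  }
  return out;
}
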