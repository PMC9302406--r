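#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Graphlet orbit counting for the 9 connected graphlets on 2-4 nodes
// (orbits 0-14, Przulj numbering). Connected induced subgraphs are
// enumerated exactly once with the ESU algorithm; each occurrence
// increments the orbit of every participating node.

namespace {

struct Graph {
  int n;
  std::vector< std::vector<int> > adj; // sorted neighbour lists, 0-based

  bool has_edge(int u, int v) const {
    const std::vector<int> &a = adj[u];
    return std::binary_search(a.begin(), a.end(), v);
  }
};

class OrbitCounter {
public:
  OrbitCounter(const Graph &g) : g_(g), orb_(g.n * 15, 0),
    in_sub_(g.n, 0), nbr_count_(g.n, 0) {}

  IntegerMatrix run() {
    // orbit 0: degree
    for (int v = 0; v < g_.n; ++v) orb_[v * 15 + 0] = (int) g_.adj[v].size();
    for (int k = 3; k <= 4; ++k) {
      k_ = k;
      for (int v = 0; v < g_.n; ++v) {
        root_ = v;
        std::vector<int> ext;
        for (int u : g_.adj[v]) if (u > v) ext.push_back(u);
        enter(v);
        sub_.push_back(v);
        extend(ext);
        sub_.pop_back();
        leave(v);
      }
    }
    IntegerMatrix out(g_.n, 15);
    for (int v = 0; v < g_.n; ++v)
      for (int o = 0; o < 15; ++o) out(v, o) = orb_[v * 15 + o];
    return out;
  }

private:
  const Graph &g_;
  std::vector<int> orb_;
  std::vector<char> in_sub_;
  std::vector<int> nbr_count_; // #subgraph nodes adjacent to each node
  std::vector<int> sub_;
  int root_, k_;

  void enter(int w) {
    in_sub_[w] = 1;
    for (int u : g_.adj[w]) ++nbr_count_[u];
  }
  void leave(int w) {
    in_sub_[w] = 0;
    for (int u : g_.adj[w]) --nbr_count_[u];
  }

  void extend(std::vector<int> ext) {
    if ((int) sub_.size() == k_) { classify(); return; }
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> next = ext;
      // exclusive neighbours of w: not in sub, not adjacent to sub, id > root
      for (int u : g_.adj[w])
        if (u > root_ && !in_sub_[u] && nbr_count_[u] == 0) next.push_back(u);
      enter(w);
      sub_.push_back(w);
      extend(next);
      sub_.pop_back();
      leave(w);
    }
  }

  void bump(int v, int o) { ++orb_[v * 15 + o]; }

  void classify() {
    if (k_ == 3) classify3(); else classify4();
  }

  void classify3() {
    int a = sub_[0], b = sub_[1], c = sub_[2];
    bool ab = g_.has_edge(a, b), ac = g_.has_edge(a, c), bc = g_.has_edge(b, c);
    int m = (int) ab + ac + bc;
    if (m == 3) {            // triangle
      bump(a, 3); bump(b, 3); bump(c, 3);
    } else {                 // path on 3 nodes
      int center = ab ? (ac ? a : b) : c;
      for (int v : sub_) bump(v, v == center ? 2 : 1);
    }
  }

  void classify4() {
    int deg[4] = {0, 0, 0, 0};
    int m = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i + 1; j < 4; ++j)
        if (g_.has_edge(sub_[i], sub_[j])) { ++deg[i]; ++deg[j]; ++m; }
    int maxdeg = *std::max_element(deg, deg + 4);
    for (int i = 0; i < 4; ++i) {
      int v = sub_[i], d = deg[i];
      switch (m) {
      case 3:
        if (maxdeg == 3) bump(v, d == 3 ? 7 : 6);        // claw
        else             bump(v, d == 1 ? 4 : 5);        // path
        break;
      case 4:
        if (maxdeg == 3) bump(v, d == 3 ? 11 : (d == 1 ? 9 : 10)); // paw
        else             bump(v, 8);                     // 4-cycle
        break;
      case 5:
        bump(v, d == 3 ? 13 : 12);                       // diamond
        break;
      default:
        bump(v, 14);                                     // K4
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix count_orbits_cpp(IntegerMatrix edges, int n) {
  Graph g;
  g.n = n;
  g.adj.assign(n, std::vector<int>());
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    if (i < 0 || j < 0 || i >= n || j >= n || i == j)
      stop("edge (%d, %d) out of range for %d nodes", edges(e, 0), edges(e, 1), n);
    g.adj[i].push_back(j);
    g.adj[j].push_back(i);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(g.adj[v].begin(), g.adj[v].end());
    g.adj[v].erase(std::unique(g.adj[v].begin(), g.adj[v].end()), g.adj[v].end());
  }
  OrbitCounter oc(g);
  return oc.run();
}

// Global order-preserving alignment of two node sequences by dynamic
// programming (Needleman-Wunsch recurrence over a node-similarity matrix).
// Ties prefer matching over gapping, then gapping in the first graph,
// for a deterministic traceback.

// [[Rcpp::export]]
List align_dp_cpp(NumericMatrix sim, double gap) {
  int n1 = sim.nrow(), n2 = sim.ncol();
  std::vector<double> prev(n2 + 1), cur(n2 + 1);
  std::vector< std::vector<unsigned char> > tb(n1 + 1, std::vector<unsigned char>(n2 + 1, 0));
  // tb codes: 1 diagonal (match), 2 up (gap in graph 2), 3 left (gap in graph 1)
  for (int j = 1; j <= n2; ++j) { prev[j] = prev[j - 1] + gap; tb[0][j] = 3; }
  for (int i = 1; i <= n1; ++i) {
    cur[0] = prev[0] + gap;
    tb[i][0] = 2;
    for (int j = 1; j <= n2; ++j) {
      double d = prev[j - 1] + sim(i - 1, j - 1);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      if (d >= u && d >= l)      { cur[j] = d; tb[i][j] = 1; }
      else if (u >= l)           { cur[j] = u; tb[i][j] = 2; }
      else                       { cur[j] = l; tb[i][j] = 3; }
    }
    std::swap(prev, cur);
  }
  double total = prev[n2];
  // traceback
  std::vector<int> mi, mj;
  double matched = 0.0;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    unsigned char t = tb[i][j];
    if (t == 1)      { mi.push_back(i); mj.push_back(j); matched += sim(i - 1, j - 1); --i; --j; }
    else if (t == 2) { --i; }
    else             { --j; }
  }
  int k = (int) mi.size();
  IntegerMatrix map(k, 2);
  for (int r = 0; r < k; ++r) { // reverse into increasing order
    map(r, 0) = mi[k - 1 - r];
    map(r, 1) = mj[k - 1 - r];
  }
  return List::create(_["objective"] = total,
                      _["matched_similarity"] = matched,
                      _["mapping"] = map);
}
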