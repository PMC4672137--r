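// Boykov-Kolmogorov augmenting-tree max-flow / min-cut for grid graphs.
// Undirected n-links are stored as antiparallel arc pairs with equal initial
// residual capacity; terminal capacities are pre-pushed so each node carries a
// single signed terminal residual.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

const int PARENT_NONE = -1;   // free or orphan
const int PARENT_TERM = -2;   // rooted directly at source/sink
enum Tree { FREE = 0, TREE_S = 1, TREE_T = 2 };

struct BKGraph {
  int n;
  std::vector<int> first;           // head of per-node arc list
  std::vector<int> nxt, to;         // arc lists; sister of arc a is a ^ 1
  std::vector<double> rcap;         // residual capacity per arc
  std::vector<double> tr;           // >0: residual from source; <0: residual to sink
  std::vector<signed char> tree;
  std::vector<int> parent;          // arc from node to its parent, or sentinel
  std::vector<int> ts, dist;        // timestamp + cached distance-to-root
  std::deque<int> active;
  std::vector<char> in_active;
  std::deque<int> orphans;
  int time;

  explicit BKGraph(int n_) : n(n_), first(n_, -1), tr(n_, 0.0),
      tree(n_, FREE), parent(n_, PARENT_NONE), ts(n_, 0), dist(n_, 0),
      in_active(n_, 0), time(0) {}

  void add_edge(int a, int b, double cap) {
    int ia = (int)to.size();
    to.push_back(b); nxt.push_back(first[a]); rcap.push_back(cap); first[a] = ia;
    int ib = (int)to.size();
    to.push_back(a); nxt.push_back(first[b]); rcap.push_back(cap); first[b] = ib;
  }

  void set_active(int i) {
    if (!in_active[i]) { in_active[i] = 1; active.push_back(i); }
  }

  int next_active() {
    while (!active.empty()) {
      int i = active.front();
      active.pop_front();
      in_active[i] = 0;
      if (tree[i] != FREE) return i;
    }
    return -1;
  }

  // distance from i to its terminal through parent pointers; -1 if cut off.
  int origin_dist(int i) {
    int d = 0, j = i;
    while (true) {
      if (ts[j] == time) { d += dist[j]; break; }
      int pa = parent[j];
      if (pa == PARENT_TERM) { break; }
      if (pa == PARENT_NONE) return -1;
      j = to[pa]; ++d;
    }
    // cache distances along the walked prefix
    int dd = d, k = i;
    while (ts[k] != time) {
      ts[k] = time; dist[k] = dd; --dd;
      int pa = parent[k];
      if (pa == PARENT_TERM) break;
      k = to[pa];
    }
    return d;
  }

  void adopt(int i) {
    signed char side = tree[i];
    int best_arc = PARENT_NONE, best_d = INT_MAX;
    for (int a = first[i]; a != -1; a = nxt[a]) {
      int j = to[a];
      if (tree[j] != side) continue;
      // capacity must point toward i for S (j -> i), away for T (i -> j)
      double cap = (side == TREE_S) ? rcap[a ^ 1] : rcap[a];
      if (cap <= 0) continue;
      int d = origin_dist(j);
      if (d >= 0 && d < best_d) { best_d = d; best_arc = a; }
    }
    if (best_arc != PARENT_NONE) {
      parent[i] = best_arc;
      ts[i] = time; dist[i] = best_d + 1;
      return;
    }
    // no parent: i leaves the tree; neighbors may become active, children orphan
    for (int a = first[i]; a != -1; a = nxt[a]) {
      int j = to[a];
      if (tree[j] != side) continue;
      double cap = (side == TREE_S) ? rcap[a ^ 1] : rcap[a];
      if (cap > 0) set_active(j);
      if (parent[j] >= 0 && to[parent[j]] == i) {
        parent[j] = PARENT_NONE;
        orphans.push_back(j);
      }
    }
    tree[i] = FREE;
  }

  void process_orphans() {
    while (!orphans.empty()) {
      int i = orphans.front();
      orphans.pop_front();
      if (tree[i] != FREE) adopt(i);
    }
  }

  // connecting arc a runs S-node -> T-node with rcap[a] > 0
  double augment(int a) {
    double f = rcap[a];
    int i = to[a ^ 1];  // S endpoint
    while (parent[i] != PARENT_TERM) {
      int b = parent[i];
      f = std::min(f, rcap[b ^ 1]);
      i = to[b];
    }
    f = std::min(f, tr[i]);
    int j = to[a];      // T endpoint
    while (parent[j] != PARENT_TERM) {
      int b = parent[j];
      f = std::min(f, rcap[b]);
      j = to[b];
    }
    f = std::min(f, -tr[j]);

    rcap[a] -= f; rcap[a ^ 1] += f;
    i = to[a ^ 1];
    while (parent[i] != PARENT_TERM) {
      int b = parent[i];
      rcap[b ^ 1] -= f; rcap[b] += f;
      int up = to[b];
      if (rcap[b ^ 1] <= 0) { parent[i] = PARENT_NONE; orphans.push_back(i); }
      i = up;
    }
    tr[i] -= f;
    if (tr[i] <= 0) { parent[i] = PARENT_NONE; orphans.push_back(i); }
    j = to[a];
    while (parent[j] != PARENT_TERM) {
      int b = parent[j];
      rcap[b] -= f; rcap[b ^ 1] += f;
      int up = to[b];
      if (rcap[b] <= 0) { parent[j] = PARENT_NONE; orphans.push_back(j); }
      j = up;
    }
    tr[j] += f;
    if (tr[j] >= 0) { parent[j] = PARENT_NONE; orphans.push_back(j); }
    return f;
  }

  double run() {
    double flow = 0.0;
    for (int i = 0; i < n; ++i) {
      if (tr[i] > 0) { tree[i] = TREE_S; parent[i] = PARENT_TERM; set_active(i); }
      else if (tr[i] < 0) { tree[i] = TREE_T; parent[i] = PARENT_TERM; set_active(i); }
    }
    ++time;
    while (true) {
      int i = next_active();
      if (i < 0) break;
      int conn = -1;
      for (int a = first[i]; a != -1; a = nxt[a]) {
        int j = to[a];
        if (tree[i] == TREE_S) {
          if (rcap[a] <= 0) continue;
          if (tree[j] == FREE) {
            tree[j] = TREE_S; parent[j] = a ^ 1;
            ts[j] = ts[i]; dist[j] = dist[i] + 1;
            set_active(j);
          } else if (tree[j] == TREE_T) { conn = a; break; }
        } else {  // TREE_T
          if (rcap[a ^ 1] <= 0) continue;
          if (tree[j] == FREE) {
            tree[j] = TREE_T; parent[j] = a ^ 1;
            ts[j] = ts[i]; dist[j] = dist[i] + 1;
            set_active(j);
          } else if (tree[j] == TREE_S) { conn = a ^ 1; break; }
        }
      }
      if (conn >= 0) {
        set_active(i);  // keep growing from i next round
        flow += augment(conn);
        ++time;
        process_orphans();
      }
    }
    return flow;
  }
};

}  // namespace

// edges: 0-based node-pair matrix; ncap: per-edge capacity; scap/tcap: terminal
// capacities. Returns source-side labels and the max-flow value.
// [[Rcpp::export(name = ".maxflow_bk")]]
List maxflow_bk(IntegerMatrix edges, NumericVector ncap,
                NumericVector scap, NumericVector tcap) {
  int n = scap.size();
  if (tcap.size() != n) stop("terminal capacity lengths differ");
  if (edges.nrow() != ncap.size()) stop("edge/capacity lengths differ");
  BKGraph g(n);
  double flow = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = scap[i], t = tcap[i];
    if (s < 0 || t < 0) stop("negative terminal capacity");
    flow += std::min(s, t);
    g.tr[i] = s - t;
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a < 0 || a >= n || b < 0 || b >= n) stop("edge endpoint out of range");
    if (ncap[e] < 0) stop("negative edge capacity");
    if (ncap[e] > 0 && a != b) g.add_edge(a, b, ncap[e]);
  }
  flow += g.run();
  LogicalVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = (g.tree[i] == TREE_S);
  return List::create(_["label"] = lab, _["flow"] = flow);
}
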