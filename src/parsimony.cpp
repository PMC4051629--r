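#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// Unordered-character (Fitch/Hartigan) parsimony kernels.
//
// Character states are bitmasks over the symbols 0-9 (bit s = state s).
// A missing cell enters as the union of the states observed in its column,
// which is equivalent to the universal set for counting purposes.

static const int MAXSTATE = 10;

// ---------------------------------------------------------------------------
// Hartigan bottom-up pass on an arbitrary rooted/unrooted ape edge matrix.
// Exact for multifurcating trees; reduces to Fitch on binary nodes.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List hartigan_score_cpp(IntegerMatrix edge, int ntip, IntegerMatrix masks,
                        NumericVector weights) {
  const int nedge = edge.nrow();
  const int nchar = masks.ncol();
  int nnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }

  std::vector< std::vector<int> > kids(nnode + 1);
  std::vector<char> ischild(nnode + 1, 0);
  for (int e = 0; e < nedge; ++e) {
    kids[edge(e, 0)].push_back(edge(e, 1));
    ischild[edge(e, 1)] = 1;
  }
  int root = -1;
  for (int v = ntip + 1; v <= nnode; ++v)
    if (!ischild[v] && !kids[v].empty()) { root = v; break; }
  if (root < 0) stop("could not locate the root of the edge matrix");

  // postorder: reverse of a preorder stack traversal
  std::vector<int> order;
  order.reserve(nnode);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < kids[v].size(); ++i) stack.push_back(kids[v][i]);
  }

  IntegerVector steps(nchar);
  double total = 0.0;
  std::vector<unsigned> set(nnode + 1);

  for (int j = 0; j < nchar; ++j) {
    int st = 0;
    for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
      int v = order[oi];
      if (v <= ntip) { set[v] = (unsigned)masks(v - 1, j); continue; }
      int cnt[MAXSTATE] = {0};
      int deg = (int)kids[v].size();
      for (int ci = 0; ci < deg; ++ci) {
        unsigned m = set[kids[v][ci]];
        for (int s = 0; s < MAXSTATE; ++s) if (m & (1u << s)) cnt[s]++;
      }
      int K = 0;
      for (int s = 0; s < MAXSTATE; ++s) if (cnt[s] > K) K = cnt[s];
      unsigned vm = 0;
      for (int s = 0; s < MAXSTATE; ++s) if (cnt[s] == K) vm |= (1u << s);
      set[v] = vm;
      st += deg - K;
    }
    steps[j] = st;
    total += st * weights[j];
  }

  return List::create(_["total"] = total, _["per_character"] = steps);
}

// ---------------------------------------------------------------------------
// Stepwise-insertion search engine (greedy start, exhaustive, branch and
// bound).  Taxa are 0-based rows of `masks`, already placed in the fixed
// addition order chosen by the caller.  Unrooted binary trees only; each
// topology is generated exactly once by the insertion recursion.
// ---------------------------------------------------------------------------

struct Engine {
  int n, nch;
  std::vector< std::vector<unsigned> > lm; // lm[t][j]
  std::vector<double> w;
  std::vector<double> extra;               // extra[k]: bound for taxa k..n-1
  std::vector<int> eu, ev;                 // current edge list
  int m;                                   // edges in use
  int next_internal;
  bool prune;
  double best;
  long long n_complete, n_pruned;
  unsigned long long node_budget, nodes_seen;
  int max_optima;
  bool overflow, budget_hit;
  std::vector<std::string> optima;

  // preallocated scratch for scoring (hot path)
  std::vector<int> deg_;                   // degree per node
  std::vector<int> nb_;                    // 3 neighbour slots per node
  std::vector<int> par_, post_, stk_;
  std::vector<unsigned> set_;
  std::vector< std::vector<int> > adj;     // only for newick emission

  Engine(const IntegerMatrix& masks, const NumericVector& weights)
      : n(masks.nrow()), nch(masks.ncol()) {
    lm.assign(n, std::vector<unsigned>(nch));
    for (int t = 0; t < n; ++t)
      for (int j = 0; j < nch; ++j) lm[t][j] = (unsigned)masks(t, j);
    w.assign(weights.begin(), weights.end());
    eu.assign(2 * n, 0); ev.assign(2 * n, 0);
    adj.assign(2 * n, std::vector<int>());
    deg_.assign(2 * n, 0); nb_.assign(6 * n, 0);
    par_.assign(2 * n, -2); post_.assign(2 * n, 0); stk_.assign(2 * n, 0);
    set_.assign(2 * n, 0u);
    m = 0; next_internal = n;
    prune = false; best = R_PosInf;
    n_complete = 0; n_pruned = 0;
    nodes_seen = 0; node_budget = ~0ULL;
    max_optima = 100000; overflow = false; budget_hit = false;
  }

  void init3() {
    int c = next_internal++;            // hub joining taxa 0,1,2
    eu[0] = c; ev[0] = 0;
    eu[1] = c; ev[1] = 1;
    eu[2] = c; ev[2] = 2;
    m = 3;
  }

  // score the current tree (k placed taxa), rooted at leaf 0
  double score(int k) {
    (void)k;
    int top = next_internal;            // node ids < top are live
    for (int v = 0; v < top; ++v) deg_[v] = 0;
    for (int e = 0; e < m; ++e) {
      int a = eu[e], b = ev[e];
      nb_[3 * a + deg_[a]++] = b;
      nb_[3 * b + deg_[b]++] = a;
    }
    // iterative preorder from leaf 0; postorder = reverse
    int np = 0, ns = 0;
    for (int v = 0; v < top; ++v) par_[v] = -2;
    par_[0] = -1;
    stk_[ns++] = 0;
    while (ns) {
      int v = stk_[--ns];
      post_[np++] = v;
      for (int i = 0; i < deg_[v]; ++i) {
        int u = nb_[3 * v + i];
        if (par_[u] == -2) { par_[u] = v; stk_[ns++] = u; }
      }
    }
    double tot = 0.0;
    int rchild = nb_[0];                // leaf 0's single neighbour
    for (int j = 0; j < nch; ++j) {
      int st = 0;
      for (int oi = np - 1; oi >= 0; --oi) {
        int v = post_[oi];
        if (v < n) { set_[v] = lm[v][j]; continue; }
        unsigned acc = 0; bool first = true;
        for (int i = 0; i < deg_[v]; ++i) {
          int u = nb_[3 * v + i];
          if (u == par_[v]) continue;
          if (first) { acc = set_[u]; first = false; }
          else {
            unsigned inter = acc & set_[u];
            if (inter) acc = inter; else { acc |= set_[u]; ++st; }
          }
        }
        set_[v] = acc;
      }
      if (!(set_[rchild] & lm[0][j])) ++st;
      tot += st * w[j];
    }
    return tot;
  }

  std::string newick_sub(int v, int from) {
    if (v < n) {
      char buf[16];
      snprintf(buf, sizeof(buf), "t%d", v + 1);
      return std::string(buf);
    }
    std::string s = "(";
    bool first = true;
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int u = adj[v][i];
      if (u == from) continue;
      if (!first) s += ",";
      s += newick_sub(u, v);
      first = false;
    }
    s += ")";
    return s;
  }

  std::string newick() {
    int top = next_internal;
    for (int v = 0; v < top; ++v) adj[v].clear();
    for (int e = 0; e < m; ++e) {
      adj[eu[e]].push_back(ev[e]);
      adj[ev[e]].push_back(eu[e]);
    }
    int hub = adj[0][0];
    std::string s = "(t1," ;
    bool first = true;
    std::string inner;
    for (size_t i = 0; i < adj[hub].size(); ++i) {
      int u = adj[hub][i];
      if (u == 0) continue;
      if (!first) inner += ",";
      inner += newick_sub(u, hub);
      first = false;
    }
    s += inner; s += ");";
    return s;
  }

  void record(double len) {
    ++n_complete;
    if (len < best - 1e-9) {
      best = len;
      optima.clear();
      overflow = false;
    }
    if (len <= best + 1e-9) {
      if ((int)optima.size() < max_optima) optima.push_back(newick());
      else overflow = true;
    }
  }

  void rec(int k) {
    if (budget_hit) return;
    if ((++nodes_seen & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    if (nodes_seen > node_budget) { budget_hit = true; return; }
    int m0 = m;
    for (int e = 0; e < m0; ++e) {
      int u = eu[e], v = ev[e];
      int wnode = next_internal++;
      ev[e] = wnode;
      eu[m] = wnode; ev[m] = v; ++m;
      eu[m] = wnode; ev[m] = k; ++m;
      double len = score(k + 1);
      if (k + 1 == n) {
        record(len);
      } else {
        if (prune && len + extra[k + 1] > best + 1e-9) ++n_pruned;
        else rec(k + 1);
      }
      m -= 2; --next_internal;
      eu[e] = u; ev[e] = v;
      if (budget_hit) return;
    }
  }
};

static void fill_extra(Engine& eng, const IntegerMatrix& bound_masks) {
  int n = eng.n, nch = eng.nch;
  eng.extra.assign(n + 1, 0.0);
  for (int j = 0; j < nch; ++j) {
    std::vector<unsigned> suf(n + 1, 0u);
    for (int t = n - 1; t >= 0; --t)
      suf[t] = suf[t + 1] | (unsigned)bound_masks(t, j);
    unsigned pre = 0u;
    for (int k = 0; k <= n; ++k) {
      unsigned nw = suf[k] & ~pre;
      int c = 0;
      while (nw) { c += nw & 1u; nw >>= 1; }
      eng.extra[k] += c * eng.w[j];
      if (k < n) pre |= (unsigned)bound_masks(k, j);
    }
  }
}

// [[Rcpp::export]]
List bnb_cpp(IntegerMatrix masks, IntegerMatrix bound_masks, NumericVector weights,
             double init_upper, bool prune, int max_optima, double node_budget) {
  int n = masks.nrow();
  if (n < 3) stop("need at least 3 taxa");
  Engine eng(masks, weights);
  eng.prune = prune;
  eng.max_optima = max_optima;
  if (R_finite(node_budget) && node_budget > 0)
    eng.node_budget = (unsigned long long)node_budget;
  fill_extra(eng, bound_masks);
  eng.init3();
  if (R_finite(init_upper)) eng.best = init_upper;
  if (n == 3) {
    double len = eng.score(3);
    eng.record(len);
  } else {
    eng.rec(3);
  }
  return List::create(
      _["best"] = eng.best,
      _["trees"] = wrap(eng.optima),
      _["n_complete"] = (double)eng.n_complete,
      _["n_pruned"] = (double)eng.n_pruned,
      _["overflow"] = eng.overflow,
      _["budget_hit"] = eng.budget_hit);
}

// Greedy stepwise addition: insert each successive taxon at the cheapest
// edge (first encountered on ties).  Supplies the initial upper bound.
// [[Rcpp::export]]
List greedy_cpp(IntegerMatrix masks, NumericVector weights) {
  int n = masks.nrow();
  if (n < 3) stop("need at least 3 taxa");
  Engine eng(masks, weights);
  eng.init3();
  double len = eng.score(3);
  for (int k = 3; k < n; ++k) {
    int bestE = -1; double bestLen = R_PosInf;
    int m0 = eng.m;
    for (int e = 0; e < m0; ++e) {
      int u = eng.eu[e], v = eng.ev[e];
      int wnode = eng.next_internal++;
      eng.ev[e] = wnode;
      eng.eu[eng.m] = wnode; eng.ev[eng.m] = v; ++eng.m;
      eng.eu[eng.m] = wnode; eng.ev[eng.m] = k; ++eng.m;
      double l = eng.score(k + 1);
      if (l < bestLen - 1e-9) { bestLen = l; bestE = e; }
      eng.m -= 2; --eng.next_internal;
      eng.eu[e] = u; eng.ev[e] = v;
    }
    // commit
    int u = eng.eu[bestE], v = eng.ev[bestE];
    (void)u;
    int wnode = eng.next_internal++;
    eng.ev[bestE] = wnode;
    eng.eu[eng.m] = wnode; eng.ev[eng.m] = v; ++eng.m;
    eng.eu[eng.m] = wnode; eng.ev[eng.m] = k; ++eng.m;
    len = bestLen;
  }
  return List::create(_["length"] = len, _["tree"] = eng.newick());
}
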