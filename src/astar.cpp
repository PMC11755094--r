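// A* search over the alignment graph of a POA graph and a query sequence.
//
// States are <layer, node, query offset>. Under the gap-linear model there is
// a single (match) layer with direct indel edges of cost dg; under the
// gap-affine model the M/I/D layers follow the Gotoh-on-graph construction:
// opening costs do+de, extension de, closing back into M free. Matches cost
// zero, which licenses (a) depth-first greedy extension of match chains and
// (b) superbubble-informed pruning against implicitly opened gaps from
// already finalized states.
//
// The heuristic is admissible but not proven consistent, so a state whose
// recorded g-cost improves after it was queued is reopened; stale queue
// entries are skipped lazily.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <climits>
#include <cstdint>

using namespace Rcpp;

namespace {

enum Op : int { OP_MATCH = 0, OP_MIS = 1, OP_INS = 2, OP_DEL = 3,
                OP_CLOSE = 4, OP_END = 5 };
enum Layer : int { LM = 0, LD = 1, LI = 2 };

struct SInfo {
  int g = INT_MAX;
  long long pred = -1;
  signed char op = -1;
  bool closed = false;
};

struct QE {
  int f;
  int i;           // query offset (larger preferred on ties)
  signed char layer;
  int node;
  long long id;
  int g;
};

struct QECmp {
  bool operator()(const QE& a, const QE& b) const {
    if (a.f != b.f) return a.f > b.f;              // min f first
    if (a.i != b.i) return a.i < b.i;              // deeper into the query
    if (a.layer != b.layer) return a.layer > b.layer;  // M < D < I
    if (a.node != b.node) return a.node > b.node;  // smaller node id
    return a.g > b.g;
  }
};

class Engine {
public:
  int N, m, nu, tau;
  bool affine;
  int dx, dg, go, ge;
  std::vector<std::vector<int> > succ;  // 0-based node ids
  std::vector<int> lab;                 // label codes, -1 for virtual
  std::vector<int> q;                   // query codes, q[j] = character j+1
  std::vector<int> dmn, dmx;            // path-length bounds to tau
  // superbubble index, CSR over nodes; entries ordered innermost-first
  std::vector<int> sb_ptr, sb_exit, sb_dmin, sb_dmax;
  bool useH, useDfs, usePrune, debug;

  std::unordered_map<long long, SInfo> tab;
  std::priority_queue<QE, std::vector<QE>, QECmp> pq;
  // finalized match-layer states per node: non-dominated (offset, cost)
  std::vector<std::vector<std::pair<int, int> > > reached;
  long long nExpanded = 0, nPruned = 0, nDfs = 0;
  std::vector<std::pair<int, int> > prunedStates;

  long long sid(int layer, int v, int i) const {
    return ((long long)layer * N + v) * (m + 1) + i;
  }

  int implicitGap(int k) const {
    if (k == 0) return 0;
    return affine ? go + k * ge : k * dg;
  }

  int heur(int layer, int v, int i) const {
    if (!useH) return 0;
    int lr = m - i;
    if (v == tau) {  // only trailing insertions remain
      if (lr == 0) return 0;
      if (!affine) return lr * dg;
      return layer == LI ? lr * ge : go + lr * ge;
    }
    int ng, dir;  // dir: 0 none, 1 ins, 2 del
    if (dmx[v] - 1 < lr)      { ng = lr - (dmx[v] - 1); dir = 1; }
    else if (dmn[v] - 1 > lr) { ng = (dmn[v] - 1) - lr; dir = 2; }
    else                      { ng = 0; dir = 0; }
    if (ng == 0) return 0;
    if (!affine) return ng * dg;
    bool openPaid = (layer == LI && dir == 1) || (layer == LD && dir == 2);
    return openPaid ? ng * ge : go + ng * ge;
  }

  void relax(int layer, int v, int i, int gnew, long long pred, int op) {
    long long id = sid(layer, v, i);
    SInfo& e = tab[id];
    if (gnew < e.g) {
      e.g = gnew;
      e.pred = pred;
      e.op = (signed char)op;
      e.closed = false;
      QE qe;
      qe.f = gnew + heur(layer, v, i);
      qe.i = i;
      qe.layer = (signed char)layer;
      qe.node = v;
      qe.id = id;
      qe.g = gnew;
      pq.push(qe);
    }
  }

  // --- reached-state bookkeeping (match layer only) ----------------------
  bool dominated(int w, int j, int c) const {
    const std::vector<std::pair<int, int> >& es = reached[w];
    for (size_t k = 0; k < es.size(); ++k) {
      int gap = j >= es[k].first ? j - es[k].first : es[k].first - j;
      if (es[k].second + implicitGap(gap) <= c) return true;
    }
    return false;
  }

  void recordReached(int v, int i, int g) {
    std::vector<std::pair<int, int> >& es = reached[v];
    for (size_t k = 0; k < es.size(); ++k) {
      int gap = i >= es[k].first ? i - es[k].first : es[k].first - i;
      if (es[k].second + implicitGap(gap) <= g) return;  // dominated
    }
    std::vector<std::pair<int, int> > kept;
    kept.reserve(es.size() + 1);
    for (size_t k = 0; k < es.size(); ++k) {
      int gap = i >= es[k].first ? i - es[k].first : es[k].first - i;
      if (!(g + implicitGap(gap) <= es[k].second)) kept.push_back(es[k]);
    }
    kept.push_back(std::make_pair(i, g));
    es.swap(kept);
  }

  // --- superbubble pruning ----------------------------------------------
  // Best-case scenario <w, j> at cost c: dominated directly, or every
  // zero-cost match extension beyond it is dominated.
  bool scenarioDominated(int w, int j, int c, int depth) {
    if (dominated(w, j, c)) return true;
    if (j >= m || depth > m) return false;
    int qc = q[j];  // character consumed moving to offset j+1
    bool any = false;
    const std::vector<int>& sc = succ[w];
    for (size_t k = 0; k < sc.size(); ++k) {
      int x = sc[k];
      if (x == tau || lab[x] != qc) continue;
      any = true;
      if (!scenarioDominated(x, j + 1, c, depth + 1)) return false;
    }
    return any;
  }

  bool prunable(int v, int i, int c) {
    for (int k = sb_ptr[v]; k < sb_ptr[v + 1]; ++k) {
      int t = sb_exit[k];
      if (reached[t].empty()) continue;
      bool all = true;
      for (int d = sb_dmin[k]; d <= sb_dmax[k]; ++d) {
        int j = i + d;
        if (j > m || !scenarioDominated(t, j, c, 0)) { all = false; break; }
      }
      if (all) return true;
    }
    return false;
  }

  // --- expansion ---------------------------------------------------------
  void queueIndels(int u, int v2, int i, int g, long long uid) {
    if (affine) {
      relax(LD, v2, i, g + go + ge, uid, OP_DEL);
      if (i < m) relax(LI, u, i + 1, g + go + ge, uid, OP_INS);
    } else {
      relax(LM, v2, i, g + dg, uid, OP_DEL);
      if (i < m) relax(LM, u, i + 1, g + dg, uid, OP_INS);
    }
  }

  void expandM(int v, int i, int g, long long id) {
    const std::vector<int>& sc = succ[v];
    for (size_t k = 0; k < sc.size(); ++k) {
      int v2 = sc[k];
      if (v2 == tau) {
        // the edge toward tau carries no operation and consumes nothing;
        // any unconsumed query suffix is inserted at tau afterwards
        relax(LM, tau, i, g, id, OP_END);
        continue;
      }
      if (i < m) {
        bool hit = lab[v2] == q[i];
        relax(LM, v2, i + 1, g + (hit ? 0 : dx), id, hit ? OP_MATCH : OP_MIS);
      }
      if (affine) relax(LD, v2, i, g + go + ge, id, OP_DEL);
      else relax(LM, v2, i, g + dg, id, OP_DEL);
    }
    if (i < m) {
      if (affine) relax(LI, v, i + 1, g + go + ge, id, OP_INS);
      else relax(LM, v, i + 1, g + dg, id, OP_INS);
    }
  }

  void expandD(int v, int i, int g, long long id) {
    relax(LM, v, i, g, id, OP_CLOSE);
    const std::vector<int>& sc = succ[v];
    for (size_t k = 0; k < sc.size(); ++k) {
      if (sc[k] != tau) relax(LD, sc[k], i, g + ge, id, OP_DEL);
    }
  }

  void expandI(int v, int i, int g, long long id) {
    relax(LM, v, i, g, id, OP_CLOSE);
    if (i < m) relax(LI, v, i + 1, g + ge, id, OP_INS);
  }

  // Depth-first greedy extension of zero-cost match chains from a popped
  // match-layer state. Frontier mismatches are queued together with the
  // adjacent insertion and deletion states; an already-visited match
  // successor is not re-pushed but does trigger queuing of the indel edges.
  void dfsExtend(int v0, int i0, int g) {
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(v0, i0));
    while (!stack.empty()) {
      int u = stack.back().first;
      int i = stack.back().second;
      stack.pop_back();
      ++nDfs;
      long long uid = sid(LM, u, i);
      if (u == tau) {  // only trailing insertions are possible at tau
        if (i < m) {
          if (affine) relax(LI, tau, i + 1, g + go + ge, uid, OP_INS);
          else relax(LM, tau, i + 1, g + dg, uid, OP_INS);
        }
        continue;
      }
      const std::vector<int>& sc = succ[u];
      for (size_t k = 0; k < sc.size(); ++k) {
        int v2 = sc[k];
        if (v2 == tau) {
          relax(LM, tau, i, g, uid, OP_END);
          continue;
        }
        bool hit = (i < m) && (lab[v2] == q[i]);
        if (hit) {
          long long id2 = sid(LM, v2, i + 1);
          SInfo& e2 = tab[id2];
          if (g < e2.g || (g == e2.g && !e2.closed)) {
            e2.g = g;
            e2.pred = uid;
            e2.op = OP_MATCH;
            e2.closed = true;
            recordReached(v2, i + 1, g);
            stack.push_back(std::make_pair(v2, i + 1));
          } else {
            queueIndels(u, v2, i, g, uid);
          }
        } else {
          if (i < m) relax(LM, v2, i + 1, g + dx, uid, OP_MIS);
          queueIndels(u, v2, i, g, uid);
        }
      }
    }
  }

  List run() {
    reached.assign(N, std::vector<std::pair<int, int> >());
    relax(LM, nu, 0, 0, -1, -1);
    long long goal = sid(LM, tau, m);
    bool found = false;
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      SInfo& e = tab[top.id];
      if (e.closed || top.g > e.g) continue;
      if (top.id == goal) {
        e.closed = true;
        found = true;
        break;
      }
      int i = (int)(top.id % (m + 1));
      long long rest = top.id / (m + 1);
      int v = (int)(rest % N);
      int layer = (int)(rest / N);
      if (usePrune && layer == LM && v != nu && v != tau &&
          sb_ptr[v] < sb_ptr[v + 1] && prunable(v, i, e.g)) {
        e.closed = true;
        ++nPruned;
        if (debug) prunedStates.push_back(std::make_pair(v, i));
        continue;
      }
      e.closed = true;
      ++nExpanded;
      if (layer == LM) {
        recordReached(v, i, e.g);
        if (useDfs) dfsExtend(v, i, e.g);
        else expandM(v, i, e.g, top.id);
      } else if (layer == LD) {
        expandD(v, i, e.g, top.id);
      } else {
        expandI(v, i, e.g, top.id);
      }
    }
    if (!found) stop("alignment terminal state unreachable (invalid graph)");

    // backtrace
    std::vector<int> opv, ndv, qpv;
    long long cur = goal;
    while (cur != -1) {
      SInfo& e = tab[cur];
      int i = (int)(cur % (m + 1));
      long long rest = cur / (m + 1);
      int v = (int)(rest % N);
      if (e.op == OP_MATCH || e.op == OP_MIS) {
        opv.push_back(e.op);
        ndv.push_back(v + 1);
        qpv.push_back(i);
      } else if (e.op == OP_DEL) {
        opv.push_back(OP_DEL);
        ndv.push_back(v + 1);
        qpv.push_back(NA_INTEGER);
      } else if (e.op == OP_INS) {
        opv.push_back(OP_INS);
        ndv.push_back(NA_INTEGER);
        qpv.push_back(i);
      }
      cur = e.pred;
    }
    int K = (int)opv.size();
    IntegerMatrix ops(K, 3);
    for (int r = 0; r < K; ++r) {
      ops(r, 0) = opv[K - 1 - r];
      ops(r, 1) = ndv[K - 1 - r];
      ops(r, 2) = qpv[K - 1 - r];
    }
    IntegerMatrix pr(debug ? (int)prunedStates.size() : 0, 2);
    if (debug) {
      for (int r = 0; r < (int)prunedStates.size(); ++r) {
        pr(r, 0) = prunedStates[r].first + 1;
        pr(r, 1) = prunedStates[r].second;
      }
    }
    return List::create(
      Named("cost") = tab[goal].g,
      Named("ops") = ops,
      Named("expanded") = (double)nExpanded,
      Named("pruned") = (double)nPruned,
      Named("dfs_steps") = (double)nDfs,
      Named("pruned_states") = pr);
  }
};

}  // namespace

// [[Rcpp::export(name = ".astar_engine")]]
List astar_engine(List succ, IntegerVector labels, int nu, int tau,
                  IntegerVector dmin, IntegerVector dmax, IntegerVector query,
                  List model, IntegerVector sb_ptr, IntegerVector sb_exit,
                  IntegerVector sb_dmin, IntegerVector sb_dmax,
                  bool use_heuristic, bool use_dfs, bool use_prune,
                  bool debug) {
  Engine en;
  en.N = succ.size();
  en.m = query.size();
  en.nu = nu - 1;
  en.tau = tau - 1;
  std::string kind = as<std::string>(model["kind"]);
  en.affine = (kind == "affine");
  en.dx = as<int>(model["dx"]);
  en.dg = en.affine ? 0 : as<int>(model["dg"]);
  en.go = en.affine ? as<int>(model["do"]) : 0;
  en.ge = en.affine ? as<int>(model["de"]) : 0;
  en.succ.resize(en.N);
  for (int v = 0; v < en.N; ++v) {
    IntegerVector s = succ[v];
    en.succ[v].assign(s.begin(), s.end());
    for (size_t k = 0; k < en.succ[v].size(); ++k) en.succ[v][k] -= 1;
  }
  en.lab.assign(labels.begin(), labels.end());
  en.q.assign(query.begin(), query.end());
  en.dmn.assign(dmin.begin(), dmin.end());
  en.dmx.assign(dmax.begin(), dmax.end());
  en.sb_ptr.assign(sb_ptr.begin(), sb_ptr.end());
  en.sb_exit.assign(sb_exit.begin(), sb_exit.end());
  for (size_t k = 0; k < en.sb_exit.size(); ++k) en.sb_exit[k] -= 1;
  en.sb_dmin.assign(sb_dmin.begin(), sb_dmin.end());
  en.sb_dmax.assign(sb_dmax.begin(), sb_dmax.end());
  en.useH = use_heuristic;
  en.useDfs = use_dfs;
  en.usePrune = use_prune;
  en.debug = debug;
  return en.run();
}
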