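// Generalized Louvain optimization of multilayer modularity on the supra
// graph of node-layer vertices.  The caller supplies the per-layer modularity
// blocks B_s = A_s - gamma * k k' / (2 m_s) (including the diagonal null
// terms) as an n x n x L array plus the ordinal coupling weight omega; this
// file only maximizes the unnormalized quality
//   Q_sum = sum_{ij in same community} B_ij  +  2 * omega * #matched adjacent
// by repeated local-move sweeps and community aggregation.  Normalization by
// 2*mu happens in R.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <numeric>

using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<int> off;     // CSR offsets, size n + 1
  std::vector<int> adj;     // neighbor ids (never the vertex itself)
  std::vector<double> w;    // edge weights, parallel to adj
  std::vector<double> selfw;
};

// xorshift32: platform-independent shuffle source, deterministic under seed
inline uint32_t next_rand(uint32_t &s) {
  s ^= s << 13;
  s ^= s >> 17;
  s ^= s << 5;
  return s;
}

void shuffle_order(std::vector<int> &order, uint32_t &rng) {
  for (int i = static_cast<int>(order.size()) - 1; i > 0; --i) {
    int j = static_cast<int>(next_rand(rng) % static_cast<uint32_t>(i + 1));
    std::swap(order[i], order[j]);
  }
}

// One level of local moves.  comm holds a community id per vertex (any ints).
// Returns true if at least one vertex moved; q_sum is updated incrementally
// and appended to qhist at the end of every sweep.
bool local_moves(const Graph &g, std::vector<int> &comm, double tol,
                 int max_sweeps, uint32_t &rng, double &q_sum,
                 std::vector<double> &qhist) {
  const int n = g.n;
  std::vector<double> cw(n, 0.0);
  std::vector<char> seen(n, 0);
  std::vector<int> touched;
  touched.reserve(64);
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);

  bool any_move = false;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    shuffle_order(order, rng);
    bool moved = false;
    for (int oi = 0; oi < n; ++oi) {
      const int v = order[oi];
      const int cv = comm[v];
      touched.clear();
      if (!seen[cv]) { seen[cv] = 1; cw[cv] = 0.0; touched.push_back(cv); }
      for (int e = g.off[v]; e < g.off[v + 1]; ++e) {
        const int cu = comm[g.adj[e]];
        if (!seen[cu]) { seen[cu] = 1; cw[cu] = 0.0; touched.push_back(cu); }
        cw[cu] += g.w[e];
      }
      // first-encountered strict best gain over neighboring communities
      const double w_own = cw[cv];
      int best = cv;
      double best_w = w_own;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int c = touched[t];
        if (c != cv && cw[c] > best_w + tol) { best_w = cw[c]; best = c; }
      }
      if (best != cv) {
        comm[v] = best;
        q_sum += 2.0 * (best_w - w_own);
        moved = true;
        any_move = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) seen[touched[t]] = 0;
    }
    qhist.push_back(q_sum);
    if (!moved) break;
  }
  return any_move;
}

// Renumber communities to 0..k-1 in order of first appearance; returns k.
int renumber(std::vector<int> &comm) {
  std::vector<int> map(comm.size(), -1);
  int k = 0;
  for (size_t v = 0; v < comm.size(); ++v) {
    if (map[comm[v]] < 0) map[comm[v]] = k++;
    comm[v] = map[comm[v]];
  }
  return k;
}

Graph aggregate(const Graph &g, const std::vector<int> &comm, int k) {
  Graph a;
  a.n = k;
  a.selfw.assign(k, 0.0);
  std::vector<std::vector<int>> members(k);
  for (int v = 0; v < g.n; ++v) members[comm[v]].push_back(v);

  std::vector<double> cw(k, 0.0);
  std::vector<char> seen(k, 0);
  std::vector<int> touched;
  a.off.assign(k + 1, 0);
  std::vector<std::vector<int>> nadj(k);
  std::vector<std::vector<double>> nw(k);

  for (int c = 0; c < k; ++c) {
    touched.clear();
    double self_acc = 0.0;
    for (size_t mi = 0; mi < members[c].size(); ++mi) {
      const int v = members[c][mi];
      self_acc += g.selfw[v];
      for (int e = g.off[v]; e < g.off[v + 1]; ++e) {
        const int cu = comm[g.adj[e]];
        if (cu == c) {
          // Q_sum counts ordered pairs; each CSR visit is one ordered pair
          self_acc += g.w[e];
        } else {
          if (!seen[cu]) { seen[cu] = 1; cw[cu] = 0.0; touched.push_back(cu); }
          cw[cu] += g.w[e];
        }
      }
    }
    a.selfw[c] = self_acc;
    for (size_t t = 0; t < touched.size(); ++t) {
      nadj[c].push_back(touched[t]);
      nw[c].push_back(cw[touched[t]]);
      seen[touched[t]] = 0;
    }
  }
  for (int c = 0; c < k; ++c) a.off[c + 1] = a.off[c] + static_cast<int>(nadj[c].size());
  a.adj.reserve(a.off[k]);
  a.w.reserve(a.off[k]);
  for (int c = 0; c < k; ++c) {
    a.adj.insert(a.adj.end(), nadj[c].begin(), nadj[c].end());
    a.w.insert(a.w.end(), nw[c].begin(), nw[c].end());
  }
  return a;
}

}  // namespace

// [[Rcpp::export]]
List genlouvain_cpp(NumericVector blocks, int n, int L, double omega,
                    double tol, int max_sweeps, double seed) {
  // supra vertex id: v = i + s * n (0-based node i, layer s)
  const int N = n * L;
  Graph g;
  g.n = N;
  g.selfw.assign(N, 0.0);
  g.off.assign(N + 1, 0);

  // count neighbors: nonzero off-diagonal block entries + ordinal couplings
  const double *B = blocks.begin();
  for (int s = 0; s < L; ++s) {
    const double *Bs = B + static_cast<size_t>(s) * n * n;
    for (int i = 0; i < n; ++i) {
      int deg = 0;
      for (int j = 0; j < n; ++j)
        if (j != i && Bs[i + static_cast<size_t>(j) * n] != 0.0) ++deg;
      if (omega != 0.0) {
        if (s > 0) ++deg;
        if (s < L - 1) ++deg;
      }
      g.off[i + s * n + 1] = deg;
    }
  }
  for (int v = 0; v < N; ++v) g.off[v + 1] += g.off[v];
  g.adj.assign(g.off[N], 0);
  g.w.assign(g.off[N], 0.0);
  {
    std::vector<int> pos(g.off.begin(), g.off.end() - 1);
    for (int s = 0; s < L; ++s) {
      const double *Bs = B + static_cast<size_t>(s) * n * n;
      for (int i = 0; i < n; ++i) {
        const int v = i + s * n;
        g.selfw[v] = Bs[i + static_cast<size_t>(i) * n];
        for (int j = 0; j < n; ++j) {
          const double b = Bs[i + static_cast<size_t>(j) * n];
          if (j != i && b != 0.0) { g.adj[pos[v]] = j + s * n; g.w[pos[v]++] = b; }
        }
        if (omega != 0.0) {
          if (s > 0) { g.adj[pos[v]] = i + (s - 1) * n; g.w[pos[v]++] = omega; }
          if (s < L - 1) { g.adj[pos[v]] = i + (s + 1) * n; g.w[pos[v]++] = omega; }
        }
      }
    }
  }

  uint32_t rng = static_cast<uint32_t>(
      static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  if (rng == 0) rng = 42u;

  std::vector<int> v2g(N);
  std::iota(v2g.begin(), v2g.end(), 0);
  double q_sum = std::accumulate(g.selfw.begin(), g.selfw.end(), 0.0);
  std::vector<double> qhist;

  Graph cur = g;
  for (;;) {
    std::vector<int> comm(cur.n);
    std::iota(comm.begin(), comm.end(), 0);
    const bool moved = local_moves(cur, comm, tol, max_sweeps, rng, q_sum, qhist);
    const int k = renumber(comm);
    for (int v = 0; v < N; ++v) v2g[v] = comm[v2g[v]];
    if (!moved || k == cur.n) break;
    cur = aggregate(cur, comm, k);
  }

  IntegerMatrix labels(n, L);
  for (int s = 0; s < L; ++s)
    for (int i = 0; i < n; ++i) labels(i, s) = v2g[i + s * n];
  return List::create(_["labels"] = labels, _["q_sum"] = q_sum,
                      _["q_history"] = NumericVector(qhist.begin(), qhist.end()));
}
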