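// Greedy constrained edge-rewiring core.
//
// The histogram method fixes F1 by keeping the edge count m constant; every
// candidate move removes one existing edge and adds one absent pair. Phase 1
// (CONSTRAIN) drives the average shortest path length y into the tolerance
// band around c by accepting only strictly gap-reducing moves; phase 2
// (OPTIMISE) is the greedy conjunctive rule: accept iff F2 strictly improves
// and the gap |y - c| does not increase. Connectivity and the degree floor
// xmin hold after every accepted move.
//
// Distances are exact BFS hop counts. The all-pairs evaluation runs 64
// sources at a time with bitset frontiers, and aborts as soon as the partial
// distance sum already exceeds the largest total an acceptable move could
// have — the abort can only fire on moves that would be rejected anyway, so
// results are identical to full evaluation. An optional landmark-sampled
// screen (sample_k > 0) estimates y from sample_k random sources; every
// would-be acceptance, and the final reported y, is re-verified exactly.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <random>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline long long pair_key(int u, int v, int n) {
  if (u > v) std::swap(u, v);
  return (long long)u * n + v;
}

// unbiased bounded draw from mt19937
static inline int draw_below(std::mt19937 &rng, int k) {
  const uint32_t lim = UINT32_MAX - (UINT32_MAX % (uint32_t)k);
  uint32_t r;
  do { r = rng(); } while (r >= lim);
  return (int)(r % (uint32_t)k);
}

struct RewireState {
  int n;
  std::vector<std::vector<int>> adj;
  std::vector<int> deg;
  std::unordered_set<long long> eset;
  std::vector<std::pair<int, int>> edges;

  void add_adj(int u, int v) {
    adj[u].push_back(v);
    adj[v].push_back(u);
    deg[u]++; deg[v]++;
  }
  void remove_one(std::vector<int> &a, int v) {
    for (size_t i = 0; i < a.size(); ++i) {
      if (a[i] == v) { a[i] = a.back(); a.pop_back(); return; }
    }
  }
  void remove_adj(int u, int v) {
    remove_one(adj[u], v);
    remove_one(adj[v], u);
    deg[u]--; deg[v]--;
  }
  // replace edge at index e by (x, y)
  void apply_move(int e, int x, int y) {
    int u = edges[e].first, v = edges[e].second;
    eset.erase(pair_key(u, v, n));
    remove_adj(u, v);
    eset.insert(pair_key(x, y, n));
    add_adj(x, y);
    edges[e] = std::make_pair(x, y);
  }
};

// Exact sum of BFS distances over ordered pairs, 64 sources per pass with
// bitset frontiers. Returns -1 if disconnected, -2 if the partial sum
// exceeded `limit` (the caller treats both as rejection), else the total.
static long long distance_total(const RewireState &st,
                                std::vector<uint64_t> &reach,
                                std::vector<uint64_t> &curf,
                                std::vector<uint64_t> &nextf,
                                long long limit) {
  const int n = st.n;
  long long total = 0;
  for (int s0 = 0; s0 < n; s0 += 64) {
    const int k = (n - s0 < 64) ? (n - s0) : 64;
    const uint64_t full = (k == 64) ? ~0ull : ((1ull << k) - 1ull);
    std::fill(reach.begin(), reach.end(), 0ull);
    std::fill(curf.begin(), curf.end(), 0ull);
    for (int i = 0; i < k; ++i) {
      reach[s0 + i] = 1ull << i;
      curf[s0 + i] = 1ull << i;
    }
    long long pairs_seen = k;
    int level = 0;
    bool active = true;
    while (active) {
      ++level;
      active = false;
      long long lv = 0;
      for (int v = 0; v < n; ++v) {
        uint64_t acc = 0;
        for (int u : st.adj[v]) acc |= curf[u];
        acc &= ~reach[v];
        nextf[v] = acc;
        if (acc) {
          reach[v] |= acc;
          lv += __builtin_popcountll(acc);
          active = true;
        }
      }
      total += (long long)level * lv;
      pairs_seen += lv;
      if (total > limit) return -2;
      std::swap(curf, nextf);
    }
    if (pairs_seen < (long long)k * n) return -1;  // some source cut off
  }
  return total;
}

// landmark-sampled distance-sum estimate from k random sources (scaled to
// the ordered-pair total); connectivity still verified exactly on the first
// source's BFS
static bool aspl_sampled(const RewireState &st, std::vector<int> &dist,
                         std::vector<int> &queue, int k, std::mt19937 &rng,
                         double &y) {
  const int n = st.n;
  long long total = 0;
  for (int i = 0; i < k; ++i) {
    int s = draw_below(rng, n);
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0, seen = 1;
    queue[tail++] = s; dist[s] = 0;
    while (head < tail) {
      int u = queue[head++];
      int du = dist[u];
      for (int w : st.adj[u]) {
        if (dist[w] < 0) {
          dist[w] = du + 1;
          queue[tail++] = w;
          total += du + 1;
          ++seen;
        }
      }
    }
    if (seen < n) return false;
  }
  y = (double)total / ((double)k * (n - 1));
  return true;
}

static double f2_total(const RewireState &st, const std::vector<double> &pa,
                       const std::vector<double> &pb,
                       const std::vector<int> &block, double inv_delta) {
  double f2 = 0.0;
  for (const auto &e : st.edges) {
    int du = st.deg[e.first], dv = st.deg[e.second];
    double term = pa[du] * pb[dv] + pa[dv] * pb[du];
    if (block[e.first] != block[e.second]) term *= inv_delta;
    f2 += term;
  }
  return f2;
}

// [[Rcpp::export]]
List cpp_optimise(int n, IntegerMatrix edges0, double a, double b, int xmin,
                  double c, double tol, double max_iters, double patience,
                  int retry_limit, int seed, IntegerVector block,
                  double delta_penalty, int sample_k) {
  const int m = edges0.nrow();
  RewireState st;
  st.n = n;
  st.adj.assign(n, std::vector<int>());
  st.deg.assign(n, 0);
  st.edges.reserve(m);
  for (int e = 0; e < m; ++e) {
    int u = edges0(e, 0), v = edges0(e, 1);
    if (u < 0 || v < 0 || u >= n || v >= n || u == v)
      stop("invalid edge in initial network");
    st.edges.push_back(std::make_pair(u, v));
    st.eset.insert(pair_key(u, v, n));
    st.add_adj(u, v);
  }
  if ((int)st.eset.size() != m) stop("duplicate edges in initial network");

  std::vector<int> blk(n);
  for (int i = 0; i < n; ++i) blk[i] = block[i];
  const double inv_delta = 1.0 / delta_penalty;

  // degree -> degree^a / degree^b lookup (degrees are bounded by n-1)
  std::vector<double> pa(n), pb(n);
  for (int d = 0; d < n; ++d) {
    pa[d] = (d == 0) ? (a == 0.0 ? 1.0 : 0.0) : std::pow((double)d, a);
    pb[d] = (d == 0) ? (b == 0.0 ? 1.0 : 0.0) : std::pow((double)d, b);
  }

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> dist(n), queue(n);
  std::vector<uint64_t> reach(n), curf(n), nextf(n);
  const long long NO_LIMIT = (long long)1 << 62;
  const double n2 = (double)n * (n - 1);  // ordered pair count

  long long total_cur = distance_total(st, reach, curf, nextf, NO_LIMIT);
  if (total_cur < 0) stop("initial network is disconnected");
  double y_cur = (double)total_cur / n2;
  double f2_cur = f2_total(st, pa, pb, blk, inv_delta);
  double gap = std::fabs(y_cur - c);
  int phase = (gap <= tol) ? 2 : 1;

  std::vector<double> tr_iter, tr_phase, tr_f2, tr_y;
  long long accepted = 0;
  double patience_ct = 0;
  bool saturated = false;
  double iter = 0;
  const bool sampled = sample_k > 0;

  for (iter = 1; iter <= max_iters; ++iter) {
    int verdict = -1;  // 0 reject, 1 accept
    int tries = 0;
    // the largest acceptable distance total: y_new may not exceed c + gap
    const long long limit =
        (long long)std::floor((c + gap) * n2 + 1e-9);
    while (tries < retry_limit) {
      ++tries;
      // draw an existing edge and an absent pair; cheap legality first
      int e = draw_below(rng, m);
      int u = st.edges[e].first, v = st.edges[e].second;
      int x = draw_below(rng, n), y2 = draw_below(rng, n);
      if (x == y2) continue;
      if (st.eset.count(pair_key(x, y2, n))) continue;
      // net degree changes of the combined remove+add
      int d_u = st.deg[u] - 1 + (u == x) + (u == y2);
      int d_v = st.deg[v] - 1 + (v == x) + (v == y2);
      int d_x = st.deg[x] + 1 - (x == u) - (x == v);
      int d_y = st.deg[y2] + 1 - (y2 == u) - (y2 == v);
      if (d_u < xmin || d_v < xmin || d_x < xmin || d_y < xmin) continue;

      st.apply_move(e, x, y2);
      double f2_new = 0.0;
      if (phase == 2) {
        f2_new = f2_total(st, pa, pb, blk, inv_delta);
        if (!(f2_new > f2_cur)) {  // greedy: ties rejected
          st.apply_move(e, u, v);
          verdict = 0;
          break;
        }
      }
      double y_new;
      bool conn, ok;
      if (sampled) {
        conn = aspl_sampled(st, dist, queue, sample_k, rng, y_new);
      } else {
        long long tot = distance_total(st, reach, curf, nextf, limit);
        if (tot == -2) {  // partial sum already beyond any acceptable total
          st.apply_move(e, u, v);
          verdict = 0;
          break;
        }
        conn = tot >= 0;
        y_new = (double)tot / n2;
      }
      if (!conn) {  // disconnecting proposals are discarded and redrawn
        st.apply_move(e, u, v);
        continue;
      }
      double gap_new = std::fabs(y_new - c);
      ok = (phase == 1) ? (gap_new < gap) : (gap_new <= gap);
      if (ok && sampled) {
        // exact re-check before committing
        long long tot = distance_total(st, reach, curf, nextf, NO_LIMIT);
        conn = tot >= 0;
        y_new = (double)tot / n2;
        gap_new = std::fabs(y_new - c);
        ok = conn && ((phase == 1) ? (gap_new < gap) : (gap_new <= gap));
      }
      if (ok) {
        y_cur = y_new;
        gap = gap_new;
        f2_cur = (phase == 2) ? f2_new : f2_total(st, pa, pb, blk, inv_delta);
        verdict = 1;
      } else {
        st.apply_move(e, u, v);
        verdict = 0;
      }
      break;
    }
    if (verdict < 0) { saturated = true; break; }  // no legal move found
    if (verdict == 1) {
      ++accepted;
      patience_ct = 0;
      tr_iter.push_back(iter);
      tr_phase.push_back((double)phase);
      tr_f2.push_back(f2_cur);
      tr_y.push_back(y_cur);
      if (phase == 1 && gap <= tol) phase = 2;
    } else {
      if (++patience_ct >= patience) break;
    }
    if (((long long)iter & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // final reported y is always exact
  long long tot_final = distance_total(st, reach, curf, nextf, NO_LIMIT);
  if (tot_final < 0) stop("internal error: final network disconnected");
  y_cur = (double)tot_final / n2;
  gap = std::fabs(y_cur - c);

  IntegerMatrix out_edges(m, 2);
  for (int e = 0; e < m; ++e) {
    out_edges(e, 0) = st.edges[e].first;
    out_edges(e, 1) = st.edges[e].second;
  }
  const size_t kk = tr_iter.size();
  NumericMatrix traj(kk, 4);
  for (size_t i = 0; i < kk; ++i) {
    traj(i, 0) = tr_iter[i];
    traj(i, 1) = tr_phase[i];
    traj(i, 2) = tr_f2[i];
    traj(i, 3) = tr_y[i];
  }
  colnames(traj) = CharacterVector::create("iteration", "phase", "f2", "y");

  return List::create(
    _["edges"] = out_edges,
    _["y"] = y_cur,
    _["f2"] = f2_cur,
    _["gap"] = gap,
    _["phase"] = phase,
    _["accepted"] = (double)accepted,
    _["iterations"] = std::min(iter, max_iters),
    _["saturated"] = saturated,
    _["success"] = gap <= tol + 1e-12,
    _["trajectory"] = traj);
}

// exact all-pairs-BFS ASPL; used as the from-scratch cross-check
// [[Rcpp::export]]
double cpp_aspl(int n, IntegerMatrix edges) {
  RewireState st;
  st.n = n;
  st.adj.assign(n, std::vector<int>());
  st.deg.assign(n, 0);
  for (int e = 0; e < edges.nrow(); ++e) st.add_adj(edges(e, 0), edges(e, 1));
  std::vector<int> dist(n), queue(n);
  long long total = 0;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0, seen = 1;
    queue[tail++] = s; dist[s] = 0;
    while (head < tail) {
      int u = queue[head++];
      int du = dist[u];
      for (int w : st.adj[u]) {
        if (dist[w] < 0) {
          dist[w] = du + 1;
          queue[tail++] = w;
          total += du + 1;
          ++seen;
        }
      }
    }
    if (seen < n) stop("network is disconnected");
  }
  return (double)total / ((double)n * (n - 1));
}
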