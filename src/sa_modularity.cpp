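#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Simulated-annealing maximisation of Newman-Girvan modularity
//   M = sum_s [ l_s / L - (d_s / (2L))^2 ]
// on the unipartite view of a bipartite graph.  Cost is C = -M; proposals
// are single-node reassignments plus collective split/merge moves, accepted
// with the Metropolis rule p = min(1, exp(-dC / T)).  Uses R's RNG so runs
// are reproducible under set.seed().

namespace {

struct State {
  int n;
  const std::vector<std::vector<int> > &adj;
  double L;
  std::vector<int> mem;                  // node -> module id
  std::vector<double> l, d;              // per-module within-links, degree sum
  std::vector<std::vector<int> > members;
  std::vector<int> node_pos;             // position of node in its module list
  std::vector<int> active;               // non-empty module ids
  std::vector<int> active_pos;           // module id -> index in active, -1
  std::vector<int> free_ids;

  State(const std::vector<std::vector<int> > &a, double L_)
      : n((int)a.size()), adj(a), L(L_), mem(n), l(n, 0.0), d(n, 0.0),
        members(n), node_pos(n), active_pos(n, -1) {
    // singleton start: node i in module i
    for (int i = 0; i < n; ++i) {
      mem[i] = i;
      members[i].push_back(i);
      node_pos[i] = 0;
      d[i] = (double)adj[i].size();
      active_pos[i] = (int)active.size();
      active.push_back(i);
    }
  }

  double modularity() const {
    double M = 0.0;
    for (size_t k = 0; k < active.size(); ++k) {
      int s = active[k];
      double ds = d[s] / (2.0 * L);
      M += l[s] / L - ds * ds;
    }
    return M;
  }

  // links from node i into module s
  double links_to(int i, int s) const {
    double k = 0;
    const std::vector<int> &nb = adj[i];
    for (size_t t = 0; t < nb.size(); ++t)
      if (mem[nb[t]] == s) k += 1;
    return k;
  }

  void remove_from_module(int i) {
    int s = mem[i];
    std::vector<int> &mv = members[s];
    int p = node_pos[i];
    mv[p] = mv.back();
    node_pos[mv[p]] = p;
    mv.pop_back();
    if (mv.empty()) {
      int ap = active_pos[s];
      active[ap] = active.back();
      active_pos[active[ap]] = ap;
      active.pop_back();
      active_pos[s] = -1;
      free_ids.push_back(s);
    }
  }

  void add_to_module(int i, int s) {
    if (active_pos[s] < 0) {
      active_pos[s] = (int)active.size();
      active.push_back(s);
    }
    mem[i] = s;
    node_pos[i] = (int)members[s].size();
    members[s].push_back(i);
  }

  int fresh_module() {
    int s = free_ids.back();
    free_ids.pop_back();
    return s;
  }
};

inline bool metro_accept(double dM, double T) {
  if (dM >= 0) return true;
  return unif_rand() < std::exp(dM / T);
}

// Single-node move; returns change in M if accepted, updates state.
double single_move(State &st, double T) {
  int i = (int)std::floor(unif_rand() * st.n);
  if (i >= st.n) i = st.n - 1;
  int cur = st.mem[i];
  int na = (int)st.active.size();
  int pick = (int)std::floor(unif_rand() * (na + 1));
  int tgt;
  bool to_new = false;
  if (pick >= na) {
    if (st.members[cur].size() == 1) return 0.0;  // already a singleton
    to_new = true;
    tgt = -1;
  } else {
    tgt = st.active[pick];
    if (tgt == cur) return 0.0;
  }
  double ki = (double)st.adj[i].size();
  double k_cur = st.links_to(i, cur);
  double k_tgt = to_new ? 0.0 : st.links_to(i, tgt);
  double dt = to_new ? 0.0 : st.d[tgt];
  double dc = st.d[cur];
  double L = st.L;
  double dM = (k_tgt - k_cur) / L -
              ((dt + ki) * (dt + ki) - dt * dt +
               (dc - ki) * (dc - ki) - dc * dc) / (4.0 * L * L);
  if (!metro_accept(dM, T)) return 0.0;
  st.remove_from_module(i);
  if (to_new) tgt = st.fresh_module();
  st.add_to_module(i, tgt);
  st.l[cur] -= k_cur;
  st.d[cur] -= ki;
  st.l[tgt] += k_tgt;
  st.d[tgt] += ki;
  return dM;
}

// Merge two random modules.
double merge_move(State &st, double T) {
  int na = (int)st.active.size();
  if (na < 2) return 0.0;
  int ia = (int)std::floor(unif_rand() * na);
  int ib = (int)std::floor(unif_rand() * (na - 1));
  if (ib >= ia) ++ib;
  int a = st.active[ia], b = st.active[ib];
  // iterate the smaller module
  if (st.members[a].size() > st.members[b].size()) std::swap(a, b);
  double e_ab = 0;
  for (size_t t = 0; t < st.members[a].size(); ++t)
    e_ab += st.links_to(st.members[a][t], b);
  double L = st.L;
  double dM = e_ab / L - st.d[a] * st.d[b] / (2.0 * L * L);
  if (!metro_accept(dM, T)) return 0.0;
  // move all of a into b
  std::vector<int> nodes = st.members[a];
  for (size_t t = 0; t < nodes.size(); ++t) {
    st.remove_from_module(nodes[t]);
    st.add_to_module(nodes[t], b);
  }
  st.l[b] += st.l[a] + e_ab;
  st.d[b] += st.d[a];
  st.l[a] = 0;
  st.d[a] = 0;
  return dM;
}

// Split a random module by random bisection.
double split_move(State &st, double T, std::vector<int> &side) {
  int na = (int)st.active.size();
  int s = st.active[(int)std::floor(unif_rand() * na)];
  size_t sz = st.members[s].size();
  if (sz < 2) return 0.0;
  std::vector<int> mv = st.members[s];  // copy: member list mutates below
  // side flag: 1 = stays, 2 = moves to new module
  for (size_t t = 0; t < sz; ++t)
    side[mv[t]] = unif_rand() < 0.5 ? 1 : 2;
  // force both halves non-empty
  side[mv[0]] = 1;
  side[mv[sz - 1]] = 2;
  double lA = 0, lB = 0, dA = 0, dB = 0;
  for (size_t t = 0; t < sz; ++t) {
    int i = mv[t];
    double within = 0;
    const std::vector<int> &nb = st.adj[i];
    for (size_t u = 0; u < nb.size(); ++u)
      if (st.mem[nb[u]] == s && side[nb[u]] == side[i]) within += 1;
    if (side[i] == 1) { lA += within; dA += (double)nb.size(); }
    else              { lB += within; dB += (double)nb.size(); }
  }
  lA /= 2.0; lB /= 2.0;
  double L = st.L;
  double ds = st.d[s];
  double dM = (lA + lB - st.l[s]) / L -
              (dA * dA + dB * dB - ds * ds) / (4.0 * L * L);
  bool ok = metro_accept(dM, T);
  if (!ok) {
    for (size_t t = 0; t < sz; ++t) side[mv[t]] = 0;
    return 0.0;
  }
  std::vector<int> movers;
  for (size_t t = 0; t < sz; ++t)
    if (side[mv[t]] == 2) movers.push_back(mv[t]);
  int b = -1;
  for (size_t t = 0; t < movers.size(); ++t) {
    st.remove_from_module(movers[t]);
    if (t == 0) b = st.fresh_module();
    st.add_to_module(movers[t], b);
  }
  st.l[s] = lA; st.d[s] = dA;
  st.l[b] = lB; st.d[b] = dB;
  for (size_t t = 0; t < sz; ++t) side[mv[t]] = 0;
  return dM;
}

}  // namespace

// [[Rcpp::export]]
List sa_optimize_cpp(List adj_list, int updates_per_T, double f,
                     double cooling, double t_initial, double t_final) {
  int n = adj_list.size();
  std::vector<std::vector<int> > adj(n);
  double twoL = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i].assign(nb.begin(), nb.end());  // 0-based neighbour indices
    twoL += nb.size();
  }
  double L = twoL / 2.0;
  if (L <= 0) stop("network has no links");
  State st(adj, L);
  double M = st.modularity();

  // auto-tune T0 towards ~50% initial proposal acceptance
  double T0 = t_initial;
  if (!(T0 > 0)) {
    T0 = 1.0 / (2.0 * L);
    std::vector<double> dMs;
    for (int t = 0; t < 200; ++t) {
      // probe: evaluate a random single-node proposal without applying it
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      int cur = st.mem[i];
      int na = (int)st.active.size();
      int pick = (int)std::floor(unif_rand() * na);
      int tgt = st.active[pick];
      if (tgt == cur) continue;
      double ki = (double)adj[i].size();
      double k_cur = st.links_to(i, cur);
      double k_tgt = st.links_to(i, tgt);
      double dt = st.d[tgt], dc = st.d[cur];
      dMs.push_back((k_tgt - k_cur) / L -
                    ((dt + ki) * (dt + ki) - dt * dt +
                     (dc - ki) * (dc - ki) - dc * dc) / (4.0 * L * L));
    }
    for (int it = 0; it < 200; ++it) {
      double acc = 0;
      for (size_t t = 0; t < dMs.size(); ++t)
        acc += dMs[t] >= 0 ? 1.0 : std::exp(dMs[t] / T0);
      if (dMs.empty() || acc / dMs.size() >= 0.5) break;
      T0 *= 1.5;
    }
  }
  double Tf = t_final > 0 ? t_final : 1e-4 * T0;
  if (!(T0 > Tf) || !R_finite(T0) || !R_finite(Tf))
    stop("non-finite or inverted temperature schedule");
  if (!(cooling > 0 && cooling < 1)) stop("cooling factor must be in (0,1)");

  int n_coll = (int)std::floor(f * n + 0.5);
  std::vector<int> side(n, 0);
  double bestM = M;
  std::vector<int> best_mem = st.mem;
  int n_temps = 0;

  for (double T = T0; T > Tf; T *= cooling) {
    ++n_temps;
    for (int u = 0; u < updates_per_T; ++u) {
      M += single_move(st, T);
      if (M > bestM + 1e-12) { bestM = M; best_mem = st.mem; }
    }
    for (int u = 0; u < n_coll; ++u) {
      M += unif_rand() < 0.5 ? merge_move(st, T) : split_move(st, T, side);
      if (M > bestM + 1e-12) { bestM = M; best_mem = st.mem; }
    }
    M = st.modularity();  // guard against float drift
    if (n_temps % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // relabel best membership to 1..k in order of first appearance
  std::vector<int> relabel(n, 0);
  int k = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int s = best_mem[i];
    if (relabel[s] == 0) relabel[s] = ++k;
    out[i] = relabel[s];
  }
  return List::create(_["membership"] = out, _["modularity"] = bestM,
                      _["n_modules"] = k, _["t_initial"] = T0,
                      _["t_final"] = Tf, _["n_temps"] = n_temps);
}

// Degree-preserving randomisation of a binary bipartite matrix by
// checkerboard (2x2 swap) moves.
// [[Rcpp::export]]
List rewire_checkerboard_cpp(IntegerMatrix m, int target_swaps,
                             int max_attempts) {
  IntegerMatrix b = clone(m);
  int nr = b.nrow(), nc = b.ncol();
  int swaps = 0;
  long attempts = 0;
  while (swaps < target_swaps && attempts < (long)max_attempts) {
    ++attempts;
    int r1 = (int)std::floor(unif_rand() * nr);
    int r2 = (int)std::floor(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = (int)std::floor(unif_rand() * nc);
    int c2 = (int)std::floor(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    int a = b(r1, c1), d = b(r2, c2), x = b(r1, c2), y = b(r2, c1);
    if (a == 1 && d == 1 && x == 0 && y == 0) {
      b(r1, c1) = 0; b(r2, c2) = 0; b(r1, c2) = 1; b(r2, c1) = 1;
      ++swaps;
    } else if (a == 0 && d == 0 && x == 1 && y == 1) {
      b(r1, c1) = 1; b(r2, c2) = 1; b(r1, c2) = 0; b(r2, c1) = 0;
      ++swaps;
    }
  }
  return List::create(_["matrix"] = b, _["swaps"] = swaps,
                      _["attempts"] = attempts);
}
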