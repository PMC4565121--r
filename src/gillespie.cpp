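#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Exact event-driven (Gillespie) simulation of the fission/fusion graph.
//
// State: n fixed edges; each edge has two endpoints (edge e owns endpoints
// 2e and 2e+1). Endpoints are partitioned into nodes of degree 1 (free end),
// 2 (bulk) or 3 (branching). Reaction channels:
//   tip-to-tip fusion   : two degree-1 nodes merge          rate kp per pair
//   bulk fission        : a degree-2 node splits            rate km per node
//   tip-to-side fusion  : degree-1 + degree-2 -> degree-3   rate lp per pair
//   branch fission      : degree-3 node sheds one branch    rate lm per node
// kp and lp are the volume-scaled (effective) bimolecular rates.
// Fusing the two endpoints of one edge into the same node (a single-edge
// self-loop) is forbidden; the forbidden pairs are excluded from the
// propensities exactly (n_iso isolated edges for tip-to-tip, n_mix edges
// with endpoint degrees {1,2} for tip-to-side).

struct GState {
  int n;                                  // edges
  std::vector<int> node_of;               // endpoint -> node id
  std::vector<std::array<int, 3> > mem;   // node id -> member endpoints
  std::vector<int> deg;                   // node id -> degree (0 = free slot)
  std::vector<int> freelist;
  std::vector<std::vector<int> > bydeg;   // degree (1..3) -> node ids
  std::vector<int> pos;                   // node id -> position in bydeg list
  std::vector<int> eclass;                // edge -> 0 plain, 1 iso, 2 mixed
  long long n_iso, n_mix;

  int u(int d) const { return (int)bydeg[d - 1].size(); }

  int new_node() {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else {
      id = (int)deg.size();
      deg.push_back(0);
      mem.push_back(std::array<int, 3>());
      pos.push_back(-1);
    }
    return id;
  }
  void add_bydeg(int id) {
    pos[id] = (int)bydeg[deg[id] - 1].size();
    bydeg[deg[id] - 1].push_back(id);
  }
  void rm_bydeg(int id) {
    std::vector<int> &v = bydeg[deg[id] - 1];
    int p = pos[id], last = v.back();
    v[p] = last; pos[last] = p; v.pop_back(); pos[id] = -1;
  }
  int classify(int e) const {
    int da = deg[node_of[2 * e]], db = deg[node_of[2 * e + 1]];
    if (da == 1 && db == 1) return 1;
    if ((da == 1 && db == 2) || (da == 2 && db == 1)) return 2;
    return 0;
  }
  void class_sub(int e) {
    if (eclass[e] == 1) --n_iso; else if (eclass[e] == 2) --n_mix;
  }
  void class_add(int e) {
    eclass[e] = classify(e);
    if (eclass[e] == 1) ++n_iso; else if (eclass[e] == 2) ++n_mix;
  }
};

static void gstate_init(GState &st, int n, const IntegerVector &node_init) {
  st.n = n;
  st.node_of.assign(2 * n, -1);
  st.deg.clear(); st.mem.clear(); st.pos.clear(); st.freelist.clear();
  st.bydeg.assign(3, std::vector<int>());
  st.eclass.assign(n, 0);
  st.n_iso = 0; st.n_mix = 0;
  int m = 0;
  for (int x = 0; x < 2 * n; ++x) m = std::max(m, node_init[x] + 1);
  std::vector<std::vector<int> > members(m);
  for (int x = 0; x < 2 * n; ++x) {
    int nd = node_init[x];
    if (nd < 0) stop("invalid node assignment");
    members[nd].push_back(x);
  }
  for (int nd = 0; nd < m; ++nd) {
    int d = (int)members[nd].size();
    if (d == 0) continue;
    if (d > 3) stop("node degree exceeds 3 in initial state");
    // forbid single-edge self-loops in the initial state
    for (int i = 0; i < d; ++i)
      for (int j = i + 1; j < d; ++j)
        if ((members[nd][i] >> 1) == (members[nd][j] >> 1))
          stop("initial state contains a single-edge self-loop");
    int id = st.new_node();
    st.deg[id] = d;
    for (int i = 0; i < d; ++i) {
      st.mem[id][i] = members[nd][i];
      st.node_of[members[nd][i]] = id;
    }
    st.add_bydeg(id);
  }
  for (int x = 0; x < 2 * n; ++x)
    if (st.node_of[x] < 0) stop("endpoint missing from initial state");
  for (int e = 0; e < n; ++e) {
    st.eclass[e] = st.classify(e);
    if (st.eclass[e] == 1) ++st.n_iso; else if (st.eclass[e] == 2) ++st.n_mix;
  }
}

static inline int pick(const std::vector<int> &v) {
  int i = (int)(unif_rand() * v.size());
  if (i >= (int)v.size()) i = (int)v.size() - 1;
  return v[i];
}

// [[Rcpp::export]]
List gillespie_run_cpp(int n_edges, IntegerVector node_init,
                       double kplus, double kminus,
                       double lplus, double lminus,
                       double burn_events, double sample_events,
                       int snapshot_every = 0, double t_max = -1.0) {
  GState st;
  gstate_init(st, n_edges, node_init);

  double t = 0.0, t_sample = 0.0;
  double acc1 = 0.0, acc2 = 0.0, acc3 = 0.0;
  long long ev = 0;
  long long total = (long long)(burn_events + sample_events);
  bool absorbed = false;
  int maxdeg_seen = 0;
  for (int d = 3; d >= 1; --d) if (st.u(d) > 0) { maxdeg_seen = d; break; }

  std::vector<double> snap1, snap2, snap3;

  std::vector<int> aff;  // scratch: affected edges of an event
  aff.reserve(8);

  while (ev < total) {
    double u1 = st.u(1), u2 = st.u(2), u3 = st.u(3);
    double p1 = kplus * std::max(0.0, u1 * (u1 - 1.0) / 2.0 - (double)st.n_iso);
    double p2 = kminus * u2;
    double p3 = lplus * std::max(0.0, u1 * u2 - (double)st.n_mix);
    double p4 = lminus * u3;
    double ptot = p1 + p2 + p3 + p4;
    if (ptot <= 0.0) { absorbed = true; break; }

    double dt = exp_rand() / ptot;
    if (t_max > 0 && t + dt > t_max) {
      // stop mid-holding-time: the state at t_max is the current one
      double rem = t_max - t;
      if (ev >= (long long)burn_events) {
        acc1 += u1 * rem; acc2 += u2 * rem; acc3 += u3 * rem;
        t_sample += rem;
      }
      t = t_max;
      break;
    }
    if (ev >= (long long)burn_events) {
      acc1 += u1 * dt; acc2 += u2 * dt; acc3 += u3 * dt;
      t_sample += dt;
    }
    t += dt;

    double z = unif_rand() * ptot;
    aff.clear();

    if (z < p1) {
      // tip-to-tip fusion: two distinct degree-1 nodes, not the two ends
      // of one isolated edge
      int na, nb;
      do {
        na = pick(st.bydeg[0]);
        do { nb = pick(st.bydeg[0]); } while (nb == na);
      } while ((st.mem[na][0] >> 1) == (st.mem[nb][0] >> 1));
      int xa = st.mem[na][0], xb = st.mem[nb][0];
      aff.push_back(xa >> 1); aff.push_back(xb >> 1);
      for (int e : aff) st.class_sub(e);
      st.rm_bydeg(na); st.rm_bydeg(nb);
      st.deg[nb] = 0; st.freelist.push_back(nb);
      st.deg[na] = 2; st.mem[na][0] = xa; st.mem[na][1] = xb;
      st.node_of[xb] = na;
      st.add_bydeg(na);
      for (int e : aff) st.class_add(e);
      if (maxdeg_seen < 2) maxdeg_seen = 2;
    } else if (z < p1 + p2) {
      // bulk fission
      int nc = pick(st.bydeg[1]);
      int xa = st.mem[nc][0], xb = st.mem[nc][1];
      aff.push_back(xa >> 1); aff.push_back(xb >> 1);
      if (aff[0] == aff[1]) aff.pop_back();
      for (int e : aff) st.class_sub(e);
      st.rm_bydeg(nc);
      st.deg[nc] = 1; st.mem[nc][0] = xa; st.add_bydeg(nc);
      int nd = st.new_node();
      st.deg[nd] = 1; st.mem[nd][0] = xb; st.node_of[xb] = nd;
      st.add_bydeg(nd);
      for (int e : aff) st.class_add(e);
    } else if (z < p1 + p2 + p3) {
      // tip-to-side fusion: degree-1 + degree-2 -> degree-3; the tip's own
      // edge must not terminate in the chosen bulk node
      int nt, nc;
      do {
        nt = pick(st.bydeg[0]);
        nc = pick(st.bydeg[1]);
      } while (st.node_of[st.mem[nt][0] ^ 1] == nc);
      int xt = st.mem[nt][0];
      aff.push_back(xt >> 1);
      aff.push_back(st.mem[nc][0] >> 1);
      aff.push_back(st.mem[nc][1] >> 1);
      for (int e : aff) st.class_sub(e);
      st.rm_bydeg(nt); st.rm_bydeg(nc);
      st.deg[nt] = 0; st.freelist.push_back(nt);
      st.deg[nc] = 3; st.mem[nc][2] = xt;
      st.node_of[xt] = nc;
      st.add_bydeg(nc);
      for (int e : aff) st.class_add(e);
      if (maxdeg_seen < 3) maxdeg_seen = 3;
    } else {
      // branch fission: detach one uniformly chosen incident branch
      int nc = pick(st.bydeg[2]);
      int k = (int)(unif_rand() * 3.0); if (k > 2) k = 2;
      int xd = st.mem[nc][k];
      aff.push_back(st.mem[nc][0] >> 1);
      aff.push_back(st.mem[nc][1] >> 1);
      aff.push_back(st.mem[nc][2] >> 1);
      for (int e : aff) st.class_sub(e);
      st.rm_bydeg(nc);
      st.deg[nc] = 2;
      int w = 0;
      for (int i = 0; i < 3; ++i)
        if (i != k) st.mem[nc][w++] = st.mem[nc][i];
      st.add_bydeg(nc);
      int nd = st.new_node();
      st.deg[nd] = 1; st.mem[nd][0] = xd; st.node_of[xd] = nd;
      st.add_bydeg(nd);
      for (int e : aff) st.class_add(e);
    }
    ++ev;
    if (snapshot_every > 0 && ev > (long long)burn_events &&
        (ev - (long long)burn_events) % snapshot_every == 0) {
      snap1.push_back(st.u(1)); snap2.push_back(st.u(2)); snap3.push_back(st.u(3));
    }
  }

  // compact node relabelling for the output
  IntegerVector node_out(2 * n_edges);
  std::vector<int> relab(st.deg.size(), -1);
  int nxt = 0;
  for (int x = 0; x < 2 * n_edges; ++x) {
    int nd = st.node_of[x];
    if (relab[nd] < 0) relab[nd] = nxt++;
    node_out[x] = relab[nd];
  }

  NumericMatrix snaps(snap1.size(), 3);
  for (size_t i = 0; i < snap1.size(); ++i) {
    snaps(i, 0) = snap1[i]; snaps(i, 1) = snap2[i]; snaps(i, 2) = snap3[i];
  }

  double u_mean1 = t_sample > 0 ? acc1 / t_sample : NA_REAL;
  double u_mean2 = t_sample > 0 ? acc2 / t_sample : NA_REAL;
  double u_mean3 = t_sample > 0 ? acc3 / t_sample : NA_REAL;

  return List::create(
    _["node_of_endpoint"] = node_out,
    _["u"] = NumericVector::create(st.u(1), st.u(2), st.u(3)),
    _["u_mean"] = NumericVector::create(u_mean1, u_mean2, u_mean3),
    _["max_degree"] = maxdeg_seen,
    _["absorbed"] = absorbed,
    _["time"] = t,
    _["events"] = (double)ev,
    _["snapshots"] = snaps);
}

// connected-component sizes (in edges) of the graph encoded by an
// endpoint -> node map, via union-find over nodes
// [[Rcpp::export]]
IntegerVector component_sizes_cpp(IntegerVector node_of_endpoint) {
  int n = node_of_endpoint.size() / 2;
  int m = 0;
  for (int x = 0; x < 2 * n; ++x) m = std::max(m, node_of_endpoint[x] + 1);
  std::vector<int> par(m);
  for (int i = 0; i < m; ++i) par[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
    return i;
  };
  for (int e = 0; e < n; ++e) {
    int a = find(node_of_endpoint[2 * e]);
    int b = find(node_of_endpoint[2 * e + 1]);
    if (a != b) par[a] = b;
  }
  std::vector<int> cnt(m, 0);
  for (int e = 0; e < n; ++e) ++cnt[find(node_of_endpoint[2 * e])];
  std::vector<int> sizes;
  for (int i = 0; i < m; ++i) if (cnt[i] > 0) sizes.push_back(cnt[i]);
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());
  return wrap(sizes);
}
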