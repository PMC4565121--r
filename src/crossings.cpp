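#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Proximity analysis of a fiber array. Fibers are zero-thickness polylines;
// a "crossing" is a contiguous region of bond pairs (on two distinct chains)
// approaching closer than sigma, reported once at its minimum-distance
// location. A spatial hash grid over bond midpoints prunes candidate pairs;
// the output contract is identical to the all-pairs scan.

struct Seg { double p[3], q[3]; };

// minimum distance between segments, plus the parameters (s,t) in [0,1]
static double seg_seg_dist(const Seg &A, const Seg &B, double &s, double &t) {
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = A.q[i] - A.p[i];
    d2[i] = B.q[i] - B.p[i];
    r[i] = A.p[i] - B.p[i];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
  double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
  double denom = a * e - b * b;
  s = 0.0;
  if (denom > 1e-14) s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
  double tnom = b * s + f;
  if (tnom < 0.0) {
    t = 0.0;
    s = std::min(1.0, std::max(0.0, -c / a));
  } else if (tnom > e) {
    t = 1.0;
    s = std::min(1.0, std::max(0.0, (b - c) / a));
  } else {
    t = tnom / e;
  }
  double dx = A.p[0] + s * d1[0] - (B.p[0] + t * d2[0]);
  double dy = A.p[1] + s * d1[1] - (B.p[1] + t * d2[1]);
  double dz = A.p[2] + s * d1[2] - (B.p[2] + t * d2[2]);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// compressed cell lists over bond midpoints (cell size = `cell`)
struct BondGrid {
  std::vector<double> mx, my, mz;
  std::vector<int> chain, row;          // per (global) bond
  std::unordered_map<long long, std::vector<int> > cells;
  double cell;

  static long long key(int ix, int iy, int iz) {
    const long long off = 1 << 20;
    return (((long long)(ix + off)) << 42) |
           (((long long)(iy + off)) << 21) |
           ((long long)(iz + off));
  }

  void build(const NumericMatrix &verts, const IntegerVector &offsets,
             double cell_size) {
    cell = cell_size;
    int nc = offsets.size() - 1;
    for (int c = 0; c < nc; ++c)
      for (int v = offsets[c]; v < offsets[c + 1] - 1; ++v) {
        chain.push_back(c);
        row.push_back(v);
        double x = 0.5 * (verts(v, 0) + verts(v + 1, 0));
        double y = 0.5 * (verts(v, 1) + verts(v + 1, 1));
        double z = 0.5 * (verts(v, 2) + verts(v + 1, 2));
        mx.push_back(x); my.push_back(y); mz.push_back(z);
      }
    for (size_t g = 0; g < mx.size(); ++g)
      cells[key((int)std::floor(mx[g] / cell),
                (int)std::floor(my[g] / cell),
                (int)std::floor(mz[g] / cell))].push_back((int)g);
  }

  // visit all unordered bond pairs on distinct chains whose midpoints lie
  // within `cell` of each other in the grid sense (i.e. candidate pairs)
  template <class F>
  void for_pairs(F fn) const {
    // half-space of neighbor offsets so each cell pair is visited once
    static const int nb[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (auto &kv : cells) {
      const std::vector<int> &A = kv.second;
      // within-cell pairs
      for (size_t i = 0; i < A.size(); ++i)
        for (size_t j = i + 1; j < A.size(); ++j)
          if (chain[A[i]] != chain[A[j]]) fn(A[i], A[j]);
      // forward neighbor cells
      long long k = kv.first;
      const long long off = 1 << 20;
      int ix = (int)((k >> 42) & 0x1FFFFF) - off;
      int iy = (int)((k >> 21) & 0x1FFFFF) - off;
      int iz = (int)(k & 0x1FFFFF) - off;
      for (int d = 0; d < 13; ++d) {
        auto it = cells.find(key(ix + nb[d][0], iy + nb[d][1], iz + nb[d][2]));
        if (it == cells.end()) continue;
        for (int a : A)
          for (int b : it->second)
            if (chain[a] != chain[b]) fn(a, b);
      }
    }
  }
};

struct Cand { int bi, bj; float d; };

// [[Rcpp::export]]
DataFrame detect_crossings_cpp(NumericMatrix verts, IntegerVector offsets,
                               double sigma, double bond_length,
                               bool use_grid = true) {
  BondGrid grid;
  grid.build(verts, offsets, sigma + bond_length);
  int nb_total = (int)grid.mx.size();

  // candidates per chain pair, keyed by (ci << 24) | cj with ci < cj;
  // membership by exact segment-segment distance < sigma
  std::unordered_map<long long, std::vector<Cand> > bypair;

  auto consider = [&](int g1, int g2) {
    int a = g1, b = g2;
    if (grid.chain[a] > grid.chain[b]) std::swap(a, b);
    Seg A, B;
    int ra = grid.row[a], rb = grid.row[b];
    for (int d = 0; d < 3; ++d) {
      A.p[d] = verts(ra, d); A.q[d] = verts(ra + 1, d);
      B.p[d] = verts(rb, d); B.q[d] = verts(rb + 1, d);
    }
    double s, t;
    double dist = seg_seg_dist(A, B, s, t);
    if (dist < sigma) {
      Cand cd;
      cd.bi = ra - offsets[grid.chain[a]];
      cd.bj = rb - offsets[grid.chain[b]];
      cd.d = (float)dist;
      bypair[((long long)grid.chain[a] << 24) | grid.chain[b]].push_back(cd);
    }
  };

  if (use_grid) {
    grid.for_pairs([&](int a, int b) {
      double dx = grid.mx[a] - grid.mx[b];
      double dy = grid.my[a] - grid.my[b];
      double dz = grid.mz[a] - grid.mz[b];
      double lim = sigma + bond_length;
      if (dx * dx + dy * dy + dz * dz < lim * lim) consider(a, b);
    });
  } else {
    for (int g1 = 0; g1 < nb_total; ++g1)
      for (int g2 = g1 + 1; g2 < nb_total; ++g2)
        if (grid.chain[g1] != grid.chain[g2]) consider(g1, g2);
  }

  // merge contiguous regions per chain pair: connected components over the
  // (bi, bj) lattice with 5x5 neighborhood, linear in the candidate count
  std::vector<int> out_ci, out_cj;
  std::vector<double> out_ri, out_rj, out_r, out_d;
  for (auto &kv : bypair) {
    int ci = (int)(kv.first >> 24), cj = (int)(kv.first & 0xFFFFFF);
    std::vector<Cand> &cd = kv.second;
    std::unordered_map<long long, int> at;  // (bi,bj) -> candidate index
    at.reserve(cd.size() * 2);
    for (size_t i = 0; i < cd.size(); ++i)
      at[((long long)cd[i].bi << 24) | cd[i].bj] = (int)i;
    std::vector<char> seen(cd.size(), 0);
    std::vector<int> stack;
    for (size_t i0 = 0; i0 < cd.size(); ++i0) {
      if (seen[i0]) continue;
      // flood-fill one region, track its minimum-distance member
      int best = (int)i0;
      stack.assign(1, (int)i0);
      seen[i0] = 1;
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        if (cd[i].d < cd[best].d) best = i;
        for (int dbi = -2; dbi <= 2; ++dbi)
          for (int dbj = -2; dbj <= 2; ++dbj) {
            if (dbi == 0 && dbj == 0) continue;
            auto it = at.find(((long long)(cd[i].bi + dbi) << 24) |
                              (cd[i].bj + dbj));
            if (it != at.end() && !seen[it->second]) {
              seen[it->second] = 1;
              stack.push_back(it->second);
            }
          }
      }
      // refine the representative with the exact closest point
      Seg A, B;
      int ra = offsets[ci] + cd[best].bi, rb = offsets[cj] + cd[best].bj;
      for (int d = 0; d < 3; ++d) {
        A.p[d] = verts(ra, d); A.q[d] = verts(ra + 1, d);
        B.p[d] = verts(rb, d); B.q[d] = verts(rb + 1, d);
      }
      double s, t;
      double dist = seg_seg_dist(A, B, s, t);
      double px = 0.5 * ((1 - s) * A.p[0] + s * A.q[0] +
                         (1 - t) * B.p[0] + t * B.q[0]);
      double py = 0.5 * ((1 - s) * A.p[1] + s * A.q[1] +
                         (1 - t) * B.p[1] + t * B.q[1]);
      double pz = 0.5 * ((1 - s) * A.p[2] + s * A.q[2] +
                         (1 - t) * B.p[2] + t * B.q[2]);
      out_ci.push_back(ci + 1);
      out_cj.push_back(cj + 1);
      out_ri.push_back((cd[best].bi + s) * bond_length);
      out_rj.push_back((cd[best].bj + t) * bond_length);
      out_r.push_back(std::sqrt(px * px + py * py + pz * pz));
      out_d.push_back(dist);
    }
  }

  return DataFrame::create(_["chain_i"] = out_ci, _["chain_j"] = out_cj,
                           _["rho_i"] = out_ri, _["rho_j"] = out_rj,
                           _["r"] = out_r, _["min_dist"] = out_d);
}

// Contour-pair proximity mass per radial shell: for every unordered pair of
// bonds on distinct chains whose midpoints lie within sigma, a^2 is added to
// the shells of both midpoints. Its expectation equals the mean-field
// crossing density S_00 computed from the fiber density, which makes it the
// quantitative MC counterpart of the analytic crossing density.
// [[Rcpp::export]]
NumericVector pair_contact_profile_cpp(NumericMatrix verts, IntegerVector offsets,
                                       double sigma, double bond_length,
                                       double dr, int nbins) {
  BondGrid grid;
  grid.build(verts, offsets, sigma);
  size_t nb = grid.mx.size();
  std::vector<double> mr(nb);
  for (size_t g = 0; g < nb; ++g)
    mr[g] = std::sqrt(grid.mx[g] * grid.mx[g] + grid.my[g] * grid.my[g] +
                      grid.mz[g] * grid.mz[g]);
  std::vector<double> bins(nbins, 0.0);
  double a2 = bond_length * bond_length;
  double s2 = sigma * sigma;
  grid.for_pairs([&](int a, int b) {
    double dx = grid.mx[a] - grid.mx[b];
    double dy = grid.my[a] - grid.my[b];
    double dz = grid.mz[a] - grid.mz[b];
    if (dx * dx + dy * dy + dz * dz < s2) {
      int b1 = (int)std::floor(mr[a] / dr);
      int b2 = (int)std::floor(mr[b] / dr);
      if (b1 >= 0 && b1 < nbins) bins[b1] += a2;
      if (b2 >= 0 && b2 < nbins) bins[b2] += a2;
    }
  });
  return wrap(bins);
}

// Exact contour length per radial shell: each bond's arc length is split
// over the shells its radius range spans (the radius along a straight bond
// is a convex function of the line parameter, so the bond is cut at its
// radial minimum and each monotone piece is sliced at the shell edges).
// Unlike a bond-count histogram this resolves sub-bond radial contraction,
// which matters for stiff chains emanating coherently from the centrosome.
// [[Rcpp::export]]
NumericVector arc_length_profile_cpp(NumericMatrix verts, IntegerVector offsets,
                                     double dr, int nbins) {
  std::vector<double> bins(nbins, 0.0);
  int nc = offsets.size() - 1;
  for (int c = 0; c < nc; ++c) {
    for (int v = offsets[c]; v < offsets[c + 1] - 1; ++v) {
      double p0[3] = {verts(v, 0), verts(v, 1), verts(v, 2)};
      double d[3] = {verts(v + 1, 0) - p0[0], verts(v + 1, 1) - p0[1],
                     verts(v + 1, 2) - p0[2]};
      double a2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double blen = std::sqrt(a2);
      if (blen <= 0) continue;
      double pd = p0[0] * d[0] + p0[1] * d[1] + p0[2] * d[2];
      double p2 = p0[0] * p0[0] + p0[1] * p0[1] + p0[2] * p0[2];
      // f(t) = p2 + 2 pd t + a2 t^2 ; radial minimum at tm
      double tm = -pd / a2;
      double tcut[2] = {0.0, 1.0};
      int npiece = 1;
      double pieces[2][2] = {{0.0, 1.0}, {0.0, 0.0}};
      if (tm > 0.0 && tm < 1.0) {
        pieces[0][0] = 0.0; pieces[0][1] = tm;
        pieces[1][0] = tm;  pieces[1][1] = 1.0;
        npiece = 2;
      }
      (void)tcut;
      for (int pc = 0; pc < npiece; ++pc) {
        double ta = pieces[pc][0], tb = pieces[pc][1];
        double ra = std::sqrt(p2 + ta * (2 * pd + ta * a2));
        double rb = std::sqrt(p2 + tb * (2 * pd + tb * a2));
        double rlo = std::min(ra, rb), rhi = std::max(ra, rb);
        int blo = (int)std::floor(rlo / dr);
        int bhi = (int)std::floor(rhi / dr);
        if (blo == bhi) {
          if (blo >= 0 && blo < nbins) bins[blo] += (tb - ta) * blen;
          continue;
        }
        // slice the monotone piece at every shell edge it crosses
        double tprev = ta;
        bool increasing = rb >= ra;
        for (int e = (increasing ? blo + 1 : bhi); ; ) {
          double redge = e * dr;
          if (increasing ? (redge >= rhi) : (redge <= rlo)) break;
          // solve f(t) = redge^2 on [ta, tb]
          double cq = p2 - redge * redge;
          double disc = pd * pd - a2 * cq;
          if (disc < 0) disc = 0;
          double sq = std::sqrt(disc);
          double t1 = (-pd - sq) / a2, t2 = (-pd + sq) / a2;
          double te = (t1 >= ta - 1e-12 && t1 <= tb + 1e-12) ? t1 : t2;
          if (te < ta) te = ta;
          if (te > tb) te = tb;
          int bin = (int)std::floor(
              (increasing ? (redge - dr * 0.5) : (redge + dr * 0.5)) / dr);
          if (bin >= 0 && bin < nbins) bins[bin] += (te - tprev) * blen;
          tprev = te;
          e += increasing ? 1 : -1;
        }
        int binlast = (int)std::floor(
            0.5 * (std::sqrt(p2 + tprev * (2 * pd + tprev * a2)) +
                   (increasing ? rhi : rlo)) / dr);
        if (binlast >= 0 && binlast < nbins) bins[binlast] += (tb - tprev) * blen;
      }
    }
  }
  return wrap(bins);
}
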