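#include <Rcpp.h>
using namespace Rcpp;

// Freely rotating chain: fixed bond length a, fixed bond angle theta,
// torsion uniform on [0, 2pi). First bond lies exactly along `graft`.
// Uses R's RNG so chains are reproducible under set.seed().

static inline void normalize3(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// [[Rcpp::export]]
NumericMatrix frc_chain_cpp(int n_bonds, double a, double theta,
                            NumericVector graft) {
  if (n_bonds < 1) stop("chain must have at least one bond");
  NumericMatrix v(n_bonds + 1, 3);
  double t[3] = {graft[0], graft[1], graft[2]};
  double gn = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
  if (gn < 1e-12) stop("graft direction must be a non-zero vector");
  t[0] /= gn; t[1] /= gn; t[2] /= gn;

  const double ct = std::cos(theta), st = std::sin(theta);
  double pos[3] = {0.0, 0.0, 0.0};

  for (int k = 0; k < n_bonds; ++k) {
    if (k > 0) {
      // orthonormal frame (u, w) perpendicular to the current tangent t:
      // start from the coordinate axis least aligned with t
      double e[3] = {0.0, 0.0, 0.0};
      int imin = 0;
      if (std::fabs(t[1]) < std::fabs(t[imin])) imin = 1;
      if (std::fabs(t[2]) < std::fabs(t[imin])) imin = 2;
      e[imin] = 1.0;
      double u[3], w[3];
      cross3(e, t, u);
      normalize3(u);
      cross3(t, u, w);
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      double tn[3];
      for (int d = 0; d < 3; ++d)
        tn[d] = ct * t[d] + st * (cp * u[d] + sp * w[d]);
      normalize3(tn);  // guard against slow drift of |t|
      t[0] = tn[0]; t[1] = tn[1]; t[2] = tn[2];
    }
    for (int d = 0; d < 3; ++d) {
      pos[d] += a * t[d];
      v(k + 1, d) = pos[d];
    }
  }
  return v;
}

// Mean tangent-tangent scalar product as a function of contour lag,
// averaged over all bond pairs of all chains. verts holds the vertices of
// all chains stacked row-wise; offsets (0-based, length n_chains+1) give
// the vertex range of each chain.
// [[Rcpp::export]]
NumericVector tangent_correlation_cpp(NumericMatrix verts, IntegerVector offsets,
                                      int max_lag) {
  int nc = offsets.size() - 1;
  NumericVector acc(max_lag + 1);
  std::vector<double> cnt(max_lag + 1, 0.0);
  for (int c = 0; c < nc; ++c) {
    int v0 = offsets[c], v1 = offsets[c + 1];
    int nb = v1 - v0 - 1;  // bonds in this chain
    if (nb < 2) continue;
    std::vector<double> tx(nb), ty(nb), tz(nb);
    for (int b = 0; b < nb; ++b) {
      double dx = verts(v0 + b + 1, 0) - verts(v0 + b, 0);
      double dy = verts(v0 + b + 1, 1) - verts(v0 + b, 1);
      double dz = verts(v0 + b + 1, 2) - verts(v0 + b, 2);
      double n = std::sqrt(dx * dx + dy * dy + dz * dz);
      tx[b] = dx / n; ty[b] = dy / n; tz[b] = dz / n;
    }
    int lmax = std::min(max_lag, nb - 1);
    for (int lag = 0; lag <= lmax; ++lag) {
      double s = 0.0;
      for (int b = 0; b + lag < nb; ++b)
        s += tx[b] * tx[b + lag] + ty[b] * ty[b + lag] + tz[b] * tz[b + lag];
      acc[lag] += s;
      cnt[lag] += nb - lag;
    }
  }
  for (int lag = 0; lag <= max_lag; ++lag)
    acc[lag] = cnt[lag] > 0 ? acc[lag] / cnt[lag] : NA_REAL;
  return acc;
}
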