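// Coarse-grained bead-spring Monte Carlo engine.
//
// Model: hard spheres (radius R, contact 2R) + extended Debye-Hueckel
// electrostatics + short-ranged -eps/r^6 attraction (eps_sticky when both
// beads are sticky, else eps_generic) + harmonic bonds between consecutive
// beads. Bonded pairs keep the hard-sphere constraint but are excluded from
// the electrostatic and 1/r^6 terms. Minimum-image convention throughout;
// an optional interaction cutoff (default: none) zeroes the non-bonded
// terms beyond `cutoff` angstrom.
//
// Coordinates are kept unwrapped (chains stay whole); all distances are
// minimum-image, which for intra-chain separations below half the box is
// identical to the plain distance.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>

using namespace Rcpp;

namespace {

struct Params {
  double eps_g, eps_s;   // kJ A^6 / mol
  double eps_x;          // cross (one sticky bead) strength
  double kappa;          // 1/A
  double elpre;          // z_i z_j prefactor: e^2 NA/(4 pi eps0 eps_r (1+kR)^2), kJ A/mol
  double radius;         // A (uniform)
  double contact2;       // (2 radius)^2
  double r0, kbond;      // A, kJ/mol/A^2
  double kT;             // kJ/mol
  double cut2;           // cutoff^2 (A^2)
  double box;
  bool intra_plain;      // chain extent < box/2 guaranteed: skip min image
};

inline double mi(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

inline double dist2_mi(const double* a, const double* b, double box) {
  double dx = mi(a[0] - b[0], box);
  double dy = mi(a[1] - b[1], box);
  double dz = mi(a[2] - b[2], box);
  return dx * dx + dy * dy + dz * dz;
}

inline double dist2_plain(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

inline double eps_of(bool sti, bool stj, const Params& p) {
  if (sti && stj) return p.eps_s;
  if (sti || stj) return p.eps_x;
  return p.eps_g;
}

// Non-bonded pair energy, overlap already excluded by caller
inline double pair_u(double r2, double zz, double eps, const Params& p) {
  if (r2 >= p.cut2) return 0.0;
  double r6 = r2 * r2 * r2;
  double u = -eps / r6;
  if (zz != 0.0) {
    double r = std::sqrt(r2);
    u += p.elpre * zz * std::exp(-p.kappa * (r - 2.0 * p.radius)) / r;
  }
  return u;
}

inline double bond_u(double r, const Params& p) {
  double d = r - p.r0;
  return 0.5 * p.kbond * d * d;
}

struct System {
  int n_chains, L, N;
  std::vector<double> x;          // 3N, bead-major (x,y,z)
  std::vector<double> z;          // valences, length L (shared topology)
  std::vector<char> sticky;      // length L
  std::vector<double> cx, cy, cz, crad;  // chain centers and radii
  Params p;

  double* bead(int g) { return &x[3 * g]; }
  const double* bead(int g) const { return &x[3 * g]; }

  void update_chain_geom(int c) {
    double sx = 0, sy = 0, sz = 0;
    int o = c * L;
    for (int i = 0; i < L; ++i) {
      sx += x[3 * (o + i)];
      sy += x[3 * (o + i) + 1];
      sz += x[3 * (o + i) + 2];
    }
    cx[c] = sx / L; cy[c] = sy / L; cz[c] = sz / L;
    double m = 0;
    for (int i = 0; i < L; ++i) {
      double dx = x[3 * (o + i)] - cx[c];
      double dy = x[3 * (o + i) + 1] - cy[c];
      double dz = x[3 * (o + i) + 2] - cz[c];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m) m = d2;
    }
    crad[c] = std::sqrt(m);
  }

  double center_dist(const double* q, int c) const {
    double dx = mi(q[0] - cx[c], p.box);
    double dy = mi(q[1] - cy[c], p.box);
    double dz = mi(q[2] - cz[c], p.box);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
};

const double INF = std::numeric_limits<double>::infinity();

// Energy of one bead (global index g, trial position q) against chain d.
// Returns INF on overlap. `skip_lo`..`skip_hi` beads of chain d are skipped
// (used to skip self and bonded neighbours when d == own chain).
double bead_vs_chain(const System& S, const double* q, int li, int c, int d) {
  double u = 0;
  int o = d * S.L;
  if (d == c) {
    for (int j = 0; j < S.L; ++j) {
      int sep = j - li; if (sep < 0) sep = -sep;
      if (sep == 0) continue;
      double r2 = S.p.intra_plain ? dist2_plain(q, S.bead(o + j))
                                  : dist2_mi(q, S.bead(o + j), S.p.box);
      if (r2 < S.p.contact2) return INF;
      if (sep == 1) continue;  // bonded: hard sphere only
      u += pair_u(r2, S.z[li] * S.z[j], eps_of(S.sticky[li], S.sticky[j], S.p), S.p);
    }
  } else {
    for (int j = 0; j < S.L; ++j) {
      double r2 = dist2_mi(q, S.bead(o + j), S.p.box);
      if (r2 < S.p.contact2) return INF;
      u += pair_u(r2, S.z[li] * S.z[j], eps_of(S.sticky[li], S.sticky[j], S.p), S.p);
    }
  }
  return u;
}

// Non-bonded energy of bead (chain c, local li) at position q against the
// whole system, with chain-level distance culling. rskip = cutoff radius.
double bead_site_energy(const System& S, const double* q, int c, int li,
                        double rskip, bool& overlap) {
  double u = 0;
  for (int d = 0; d < S.n_chains; ++d) {
    if (d != c) {
      double dd = S.center_dist(q, d);
      if (dd - S.crad[d] > rskip) continue;
    }
    double v = bead_vs_chain(S, q, li, c, d);
    if (v == INF) { overlap = true; return INF; }
    u += v;
  }
  return u;
}

// Bond energy terms touching local bead li of chain c with bead position q
double bead_bond_energy(const System& S, const double* q, int c, int li) {
  double u = 0;
  int o = c * S.L;
  if (li > 0)
    u += bond_u(std::sqrt(dist2_mi(q, S.bead(o + li - 1), S.p.box)), S.p);
  if (li < S.L - 1)
    u += bond_u(std::sqrt(dist2_mi(q, S.bead(o + li + 1), S.p.box)), S.p);
  return u;
}

// Total energy by full double loop (also used to validate bookkeeping)
double total_energy_sys(const System& S, bool& overlap) {
  overlap = false;
  double u = 0;
  for (int g = 0; g < S.N; ++g) {
    int c = g / S.L, li = g % S.L;
    // pairs within chain, j > li
    int o = c * S.L;
    for (int j = li + 1; j < S.L; ++j) {
      double r2 = S.p.intra_plain ? dist2_plain(S.bead(g), S.bead(o + j))
                                  : dist2_mi(S.bead(g), S.bead(o + j), S.p.box);
      if (r2 < S.p.contact2) { overlap = true; return INF; }
      if (j == li + 1) {
        u += bond_u(std::sqrt(r2), S.p);
      } else {
        u += pair_u(r2, S.z[li] * S.z[j], eps_of(S.sticky[li], S.sticky[j], S.p), S.p);
      }
    }
    // pairs with later chains
    for (int d = c + 1; d < S.n_chains; ++d) {
      int od = d * S.L;
      for (int j = 0; j < S.L; ++j) {
        double r2 = dist2_mi(S.bead(g), S.bead(od + j), S.p.box);
        if (r2 < S.p.contact2) { overlap = true; return INF; }
        u += pair_u(r2, S.z[li] * S.z[j], eps_of(S.sticky[li], S.sticky[j], S.p), S.p);
      }
    }
  }
  return u;
}

// Non-bonded energy of chain c against all other chains (old coordinates)
double chain_inter_energy(const System& S, const std::vector<double>& ch,
                          int c, double rskip) {
  // ch: 3L trial coordinates of chain c
  double u = 0;
  // bounding sphere of the trial coordinates for chain-level culling
  double mnx = 0, mny = 0, mnz = 0;
  for (int i = 0; i < S.L; ++i) {
    mnx += ch[3 * i]; mny += ch[3 * i + 1]; mnz += ch[3 * i + 2];
  }
  mnx /= S.L; mny /= S.L; mnz /= S.L;
  double rad = 0;
  for (int i = 0; i < S.L; ++i) {
    double dx = ch[3 * i] - mnx, dy = ch[3 * i + 1] - mny, dz = ch[3 * i + 2] - mnz;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > rad) rad = d2;
  }
  rad = std::sqrt(rad);
  double q[3] = {mnx, mny, mnz};
  for (int d = 0; d < S.n_chains; ++d) {
    if (d == c) continue;
    int od = d * S.L;
    if (S.center_dist(q, d) - rad - S.crad[d] > rskip) continue;
    for (int i = 0; i < S.L; ++i) {
      const double* qi = &ch[3 * i];
      if (S.center_dist(qi, d) - S.crad[d] > rskip) continue;
      for (int j = 0; j < S.L; ++j) {
        double r2 = dist2_mi(qi, S.bead(od + j), S.p.box);
        if (r2 < S.p.contact2) return INF;
        u += pair_u(r2, S.z[i] * S.z[j], eps_of(S.sticky[i], S.sticky[j], S.p), S.p);
      }
    }
  }
  return u;
}

// Intra-chain energy (bonds + non-bonded) of trial coordinates ch
double chain_intra_energy(const System& S, const std::vector<double>& ch) {
  double u = 0;
  for (int i = 0; i < S.L; ++i) {
    for (int j = i + 1; j < S.L; ++j) {
      double r2 = S.p.intra_plain ? dist2_plain(&ch[3 * i], &ch[3 * j])
                                  : dist2_mi(&ch[3 * i], &ch[3 * j], S.p.box);
      if (r2 < S.p.contact2) return INF;
      if (j == i + 1) u += bond_u(std::sqrt(r2), S.p);
      else u += pair_u(r2, S.z[i] * S.z[j], eps_of(S.sticky[i], S.sticky[j], S.p), S.p);
    }
  }
  return u;
}

void copy_chain(const System& S, int c, std::vector<double>& ch) {
  ch.assign(S.x.begin() + 3 * c * S.L, S.x.begin() + 3 * (c + 1) * S.L);
}

void write_chain(System& S, int c, const std::vector<double>& ch) {
  std::copy(ch.begin(), ch.end(), S.x.begin() + 3 * c * S.L);
}

inline void rand_unit(double* v) {
  // Marsaglia
  double a, b, s;
  do {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s == 0.0);
  double t = 2.0 * std::sqrt(1.0 - s);
  v[0] = a * t; v[1] = b * t; v[2] = 1.0 - 2.0 * s;
}

void rotate_about(const double* axis, double ang, const double* origin,
                  double* pt) {
  // Rodrigues rotation of pt about axis through origin
  double v[3] = {pt[0] - origin[0], pt[1] - origin[1], pt[2] - origin[2]};
  double c = std::cos(ang), s = std::sin(ang);
  double k0 = axis[0], k1 = axis[1], k2 = axis[2];
  double cross[3] = {k1 * v[2] - k2 * v[1], k2 * v[0] - k0 * v[2],
                     k0 * v[1] - k1 * v[0]};
  double dot = k0 * v[0] + k1 * v[1] + k2 * v[2];
  for (int i = 0; i < 3; ++i) {
    double r = v[i] * c + cross[i] * s + (i == 0 ? k0 : (i == 1 ? k1 : k2)) * dot * (1 - c);
    pt[i] = origin[i] + r;
  }
}

// Sample a bond length from f(l) ~ l^2 exp(-beta k/2 (l-r0)^2), l >= contact
double sample_bond_length(const Params& p) {
  double sig = std::sqrt(p.kT / p.kbond);
  double lmax = p.r0 + 5.0 * sig;
  for (int it = 0; it < 1000; ++it) {
    double l = p.r0 + sig * norm_rand();
    if (l < 2.0 * p.radius || l > lmax) continue;
    if (unif_rand() < (l * l) / (lmax * lmax)) return l;
  }
  return p.r0;  // unreachable in practice
}

struct ClusterAccum {
  // per-frame accumulation of chain fractions by size class and N_ass
  double frac1 = 0, frac2 = 0, frac3 = 0, frac4p = 0, nass = 0;
  int frames = 0;
};

void cluster_frame(const System& S, double cutoff, std::vector<int>& parent) {
  int n = S.n_chains;
  parent.resize(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  double cut2 = cutoff * cutoff;
  for (int c = 0; c < n; ++c) {
    for (int d = c + 1; d < n; ++d) {
      double q[3] = {S.cx[c], S.cy[c], S.cz[c]};
      double cd = S.center_dist(q, d);
      if (cd - S.crad[c] - S.crad[d] > cutoff) continue;
      if (find(c) == find(d)) continue;
      bool contact = false;
      int oc = c * S.L, od = d * S.L;
      for (int i = 0; i < S.L && !contact; ++i)
        for (int j = 0; j < S.L; ++j)
          if (dist2_mi(S.bead(oc + i), S.bead(od + j), S.p.box) <= cut2) {
            contact = true; break;
          }
      if (contact) parent[find(c)] = find(d);
    }
  }
  for (int i = 0; i < n; ++i) parent[i] = find(i);
}

}  // namespace

// [[Rcpp::export]]
SEXP place_chains_cpp(int n_chains, int L, double box, double r0,
                      double contact, int max_tries) {
  NumericMatrix out(n_chains * L, 3);
  double contact2 = contact * contact;
  std::vector<double> placed;  // 3 * count
  int tries = 0;
  for (int c = 0; c < n_chains; ++c) {
    bool chain_ok = false;
    while (!chain_ok) {
      if (++tries > max_tries * n_chains) return R_NilValue;
      std::vector<double> ch(3 * L);
      ch[0] = unif_rand() * box;
      ch[1] = unif_rand() * box;
      ch[2] = unif_rand() * box;
      bool fail = false;
      for (int i = 0; i < L; ++i) {
        bool bead_ok = false;
        for (int att = 0; att < (i == 0 ? 1 : 60) && !bead_ok; ++att) {
          if (i > 0) {
            double u[3]; rand_unit(u);
            for (int k = 0; k < 3; ++k) ch[3 * i + k] = ch[3 * (i - 1) + k] + r0 * u[k];
          }
          bead_ok = true;
          // own chain, non-adjacent
          for (int j = 0; j + 1 < i && bead_ok; ++j)
            if (dist2_mi(&ch[3 * i], &ch[3 * j], box) < contact2) bead_ok = false;
          // previously placed chains
          for (size_t j = 0; 3 * j < placed.size() && bead_ok; ++j)
            if (dist2_mi(&ch[3 * i], &placed[3 * j], box) < contact2) bead_ok = false;
          if (i == 0 && !bead_ok) break;
        }
        if (!bead_ok) { fail = true; break; }
      }
      if (!fail) {
        for (int i = 0; i < L; ++i) {
          out(c * L + i, 0) = ch[3 * i];
          out(c * L + i, 1) = ch[3 * i + 1];
          out(c * L + i, 2) = ch[3 * i + 2];
        }
        placed.insert(placed.end(), ch.begin(), ch.end());
        chain_ok = true;
      }
    }
  }
  return out;
}

static System make_system(NumericMatrix coords, int n_chains, int L,
                          NumericVector charges, LogicalVector sticky,
                          double box, List params) {
  System S;
  S.n_chains = n_chains; S.L = L; S.N = n_chains * L;
  if (coords.nrow() != S.N || coords.ncol() != 3)
    stop("coords must be an (n_chains * n_beads) x 3 matrix");
  S.x.resize(3 * S.N);
  for (int g = 0; g < S.N; ++g)
    for (int k = 0; k < 3; ++k) S.x[3 * g + k] = coords(g, k);
  S.z.assign(charges.begin(), charges.end());
  S.sticky.resize(L);
  for (int i = 0; i < L; ++i) S.sticky[i] = sticky[i] ? 1 : 0;
  Params p;
  p.eps_g = as<double>(params["eps_generic"]);
  p.eps_s = as<double>(params["eps_sticky"]);
  p.eps_x = as<double>(params["eps_cross"]);
  p.kappa = as<double>(params["kappa"]);
  p.radius = as<double>(params["bead_radius"]);
  double elconst = as<double>(params["elconst"]);
  double den = (1.0 + p.kappa * p.radius);
  p.elpre = elconst / (den * den);
  p.contact2 = 4.0 * p.radius * p.radius;
  p.r0 = as<double>(params["r0"]);
  p.kbond = as<double>(params["k_bond"]);
  p.kT = as<double>(params["kT"]);
  double cut = as<double>(params["cutoff"]);
  if (!R_finite(cut)) cut = 0.866025403784 * 3.0 * box;  // beyond any min-image distance
  p.cut2 = cut * cut;
  p.box = box;
  // Plain intra-chain distances are exactly equivalent to minimum-image
  // ones when the largest possible chain extent (bonds can never exceed
  // ~12 A: 26 kT of stretch) plus the cutoff fits in the box.
  p.intra_plain = ((L - 1) * 12.0 + cut) <= box;
  S.p = p;
  S.cx.resize(n_chains); S.cy.resize(n_chains); S.cz.resize(n_chains);
  S.crad.resize(n_chains);
  for (int c = 0; c < n_chains; ++c) S.update_chain_geom(c);
  return S;
}

// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix coords, int n_chains, int L,
                        NumericVector charges, LogicalVector sticky,
                        double box, List params) {
  System S = make_system(coords, n_chains, L, charges, sticky, box, params);
  bool ov;
  double u = total_energy_sys(S, ov);
  return ov ? R_PosInf : u;
}

// [[Rcpp::export]]
List run_mc_cpp(NumericMatrix coords, int n_chains, int L,
                NumericVector charges, LogicalVector sticky, double box,
                List params, List config) {
  System S = make_system(coords, n_chains, L, charges, sticky, box, params);
  const Params& p = S.p;
  double rskip = std::sqrt(p.cut2);

  long eq_passes = (long)as<double>(config["equilibration"]);
  long prod_passes = (long)as<double>(config["production"]);
  int n_sub = as<int>(config["n_subdivisions"]);
  NumericVector w = config["move_weights"];  // single, pivot, trans, slither
  double amp_s = as<double>(config["amp_single"]);
  double amp_t = as<double>(config["amp_translate"]);
  double amp_p = as<double>(config["amp_pivot"]);
  bool tune = as<bool>(config["tune"]);
  int obs_stride = as<int>(config["obs_stride"]);
  int cl_stride = as<int>(config["cluster_stride"]);
  int frame_stride = as<int>(config["frame_stride"]);
  double cl_cut = as<double>(config["cluster_cutoff"]);

  if (L < 3) w[1] = 0.0;  // pivot needs an internal bead
  double wsum = w[0] + w[1] + w[2] + w[3];
  if (wsum <= 0) stop("move weights sum to zero");
  double cw[4];
  cw[0] = w[0] / wsum;
  for (int i = 1; i < 4; ++i) cw[i] = cw[i - 1] + w[i] / wsum;

  bool ov;
  double U = total_energy_sys(S, ov);
  if (ov || !R_finite(U)) stop("initial configuration has non-finite energy");

  long tries_t[4] = {0, 0, 0, 0}, acc_t[4] = {0, 0, 0, 0};
  long tune_tries[4] = {0, 0, 0, 0}, tune_acc[4] = {0, 0, 0, 0};

  // observable accumulators per subdivision
  int n_obs = 8;
  std::vector<double> sub_sum(n_sub * n_obs, 0.0);
  std::vector<long> sub_nE(n_sub, 0), sub_nC(n_sub, 0);
  std::vector<NumericMatrix> frames;
  std::vector<int> parent;
  std::vector<double> trial(3 * (size_t)L), oldch(3 * (size_t)L);

  long total_passes = eq_passes + prod_passes;
  for (long pass = 0; pass < total_passes; ++pass) {
    bool production = pass >= eq_passes;
    for (int t = 0; t < S.N; ++t) {
      double u01 = unif_rand();
      int kind = 0;
      while (kind < 3 && u01 > cw[kind]) ++kind;
      tries_t[kind]++;
      if (!production) tune_tries[kind]++;

      if (kind == 0) {
        // single-bead displacement
        int g = (int)(unif_rand() * S.N); if (g >= S.N) g = S.N - 1;
        int c = g / L, li = g % L;
        double q[3];
        for (int k = 0; k < 3; ++k)
          q[k] = S.x[3 * g + k] + amp_s * (2.0 * unif_rand() - 1.0);
        bool ov1 = false, ov0 = false;
        double unew = bead_site_energy(S, q, c, li, rskip, ov1);
        double dU;
        if (ov1) {
          dU = INF;
        } else {
          unew += bead_bond_energy(S, q, c, li);
          double uold = bead_site_energy(S, S.bead(g), c, li, rskip, ov0) +
                        bead_bond_energy(S, S.bead(g), c, li);
          dU = unew - uold;
        }
        if (dU <= 0.0 || (R_finite(dU) && unif_rand() < std::exp(-dU / p.kT))) {
          for (int k = 0; k < 3; ++k) S.x[3 * g + k] = q[k];
          U += dU;
          S.update_chain_geom(c);
          acc_t[kind]++;
          if (!production) tune_acc[kind]++;
        }
      } else if (kind == 1) {
        // pivot: rotate the shorter tail about an internal bead
        int c = (int)(unif_rand() * n_chains); if (c >= n_chains) c = n_chains - 1;
        int piv = 1 + (int)(unif_rand() * (L - 2)); if (piv > L - 2) piv = L - 2;
        copy_chain(S, c, trial);
        double axis[3]; rand_unit(axis);
        double ang = amp_p * (2.0 * unif_rand() - 1.0);
        double origin[3] = {trial[3 * piv], trial[3 * piv + 1], trial[3 * piv + 2]};
        int lo, hi;  // beads to rotate
        if (piv <= L - 2 - piv) { lo = 0; hi = piv - 1; } else { lo = piv + 1; hi = L - 1; }
        for (int i = lo; i <= hi; ++i) rotate_about(axis, ang, origin, &trial[3 * i]);
        double uold = chain_intra_energy(S, oldch = std::vector<double>(S.x.begin() + 3 * c * L, S.x.begin() + 3 * (c + 1) * L));
        double uold_inter = chain_inter_energy(S, oldch, c, rskip);
        double unew = chain_intra_energy(S, trial);
        double dU;
        if (unew == INF) dU = INF;
        else {
          double unew_inter = chain_inter_energy(S, trial, c, rskip);
          dU = (unew_inter == INF) ? INF : (unew + unew_inter) - (uold + uold_inter);
        }
        if (dU <= 0.0 || (R_finite(dU) && unif_rand() < std::exp(-dU / p.kT))) {
          write_chain(S, c, trial);
          U += dU;
          S.update_chain_geom(c);
          acc_t[kind]++;
          if (!production) tune_acc[kind]++;
        }
      } else if (kind == 2) {
        // whole-chain translation
        int c = (int)(unif_rand() * n_chains); if (c >= n_chains) c = n_chains - 1;
        double dv[3];
        for (int k = 0; k < 3; ++k) dv[k] = amp_t * (2.0 * unif_rand() - 1.0);
        copy_chain(S, c, oldch);
        trial = oldch;
        for (int i = 0; i < L; ++i)
          for (int k = 0; k < 3; ++k) trial[3 * i + k] += dv[k];
        double uold = chain_inter_energy(S, oldch, c, rskip);
        double unew = chain_inter_energy(S, trial, c, rskip);
        double dU = (unew == INF) ? INF : unew - uold;
        if (dU <= 0.0 || (R_finite(dU) && unif_rand() < std::exp(-dU / p.kT))) {
          write_chain(S, c, trial);
          U += dU;
          S.update_chain_geom(c);
          acc_t[kind]++;
          if (!production) tune_acc[kind]++;
        }
      } else {
        // slithering (reptation): remove one end bead, regrow at the other
        // with bond length drawn from the bond Boltzmann distribution, so
        // the end-bond terms cancel against the proposal density.
        int c = (int)(unif_rand() * n_chains); if (c >= n_chains) c = n_chains - 1;
        bool forward = unif_rand() < 0.5;  // forward: drop bead 0, grow after L-1
        copy_chain(S, c, oldch);
        double l_new = sample_bond_length(p);
        double u[3]; rand_unit(u);
        if (forward) {
          for (int i = 0; i + 1 < L; ++i)
            for (int k = 0; k < 3; ++k) trial[3 * i + k] = oldch[3 * (i + 1) + k];
          for (int k = 0; k < 3; ++k)
            trial[3 * (L - 1) + k] = oldch[3 * (L - 1) + k] + l_new * u[k];
        } else {
          for (int i = 1; i < L; ++i)
            for (int k = 0; k < 3; ++k) trial[3 * i + k] = oldch[3 * (i - 1) + k];
          for (int k = 0; k < 3; ++k)
            trial[3 * 0 + k] = oldch[3 * 0 + k] + l_new * u[k];
        }
        // energies excluding the regrown/removed end-bond harmonic terms
        double removed_bond, added_bond, l_removed;
        {
          const double* a; const double* b;
          if (forward) { a = &oldch[0]; b = &oldch[3]; }
          else { a = &oldch[3 * (L - 1)]; b = &oldch[3 * (L - 2)]; }
          l_removed = std::sqrt(dist2_mi(a, b, p.box));
          removed_bond = bond_u(l_removed, p);
        }
        added_bond = bond_u(l_new, p);
        // reverse move must be able to propose the removed bond length
        double sig_b = std::sqrt(p.kT / p.kbond);
        bool rev_ok = l_removed <= p.r0 + 5.0 * sig_b;
        double uold = chain_intra_energy(S, oldch) + chain_inter_energy(S, oldch, c, rskip);
        double unew_i = chain_intra_energy(S, trial);
        double dU;
        if (unew_i == INF) dU = INF;
        else {
          double unew_e = chain_inter_energy(S, trial, c, rskip);
          dU = (unew_e == INF) ? INF : (unew_i + unew_e) - uold;
        }
        // subtract the proposal-cancelled bond terms from the Metropolis test
        double dU_acc = R_finite(dU) ? dU - added_bond + removed_bond : dU;
        if (!rev_ok) dU_acc = INF;
        if (dU_acc <= 0.0 || (R_finite(dU_acc) && unif_rand() < std::exp(-dU_acc / p.kT))) {
          write_chain(S, c, trial);
          U += dU;
          S.update_chain_geom(c);
          acc_t[kind]++;
          if (!production) tune_acc[kind]++;
        }
      }
    }

    if (tune && !production && ((pass + 1) % 25 == 0)) {
      // drive per-type acceptance toward ~30%
      struct { double* amp; int idx; double lo, hi; } knobs[3] = {
        {&amp_s, 0, 0.05, box / 2}, {&amp_p, 1, 0.02, M_PI}, {&amp_t, 2, 0.5, box / 2}
      };
      for (auto& kn : knobs) {
        if (tune_tries[kn.idx] < 50) continue;
        double a = (double)tune_acc[kn.idx] / tune_tries[kn.idx];
        if (a > 0.35) *kn.amp *= 1.2;
        else if (a < 0.25) *kn.amp *= 0.85;
        if (*kn.amp < kn.lo) *kn.amp = kn.lo;
        if (*kn.amp > kn.hi) *kn.amp = kn.hi;
        tune_tries[kn.idx] = tune_acc[kn.idx] = 0;
      }
    }

    if (production) {
      long ppass = pass - eq_passes;
      int sub = (int)((ppass * (long)n_sub) / prod_passes);
      if (sub >= n_sub) sub = n_sub - 1;
      if (obs_stride > 0 && ppass % obs_stride == 0) {
        // energy, mean Rg, mean end-to-end
        double rg = 0, ree = 0;
        for (int c = 0; c < n_chains; ++c) {
          int o = c * L;
          double s2 = 0;
          for (int i = 0; i < L; ++i) {
            double dx = S.x[3 * (o + i)] - S.cx[c];
            double dy = S.x[3 * (o + i) + 1] - S.cy[c];
            double dz = S.x[3 * (o + i) + 2] - S.cz[c];
            s2 += dx * dx + dy * dy + dz * dz;
          }
          rg += std::sqrt(s2 / L);
          double dx = S.x[3 * (o + L - 1)] - S.x[3 * o];
          double dy = S.x[3 * (o + L - 1) + 1] - S.x[3 * o + 1];
          double dz = S.x[3 * (o + L - 1) + 2] - S.x[3 * o + 2];
          ree += std::sqrt(dx * dx + dy * dy + dz * dz);
        }
        sub_sum[sub * n_obs + 0] += U;
        sub_sum[sub * n_obs + 1] += rg / n_chains;
        sub_sum[sub * n_obs + 2] += ree / n_chains;
        sub_nE[sub]++;
      }
      if (cl_stride > 0 && ppass % cl_stride == 0) {
        cluster_frame(S, cl_cut, parent);
        std::vector<int> size(n_chains, 0);
        for (int i = 0; i < n_chains; ++i) size[parent[i]]++;
        int ncl = 0; double f1 = 0, f2 = 0, f3 = 0, f4 = 0;
        for (int i = 0; i < n_chains; ++i) {
          if (size[i] == 0) continue;
          ncl++;
          if (size[i] == 1) f1 += 1;
          else if (size[i] == 2) f2 += 2;
          else if (size[i] == 3) f3 += 3;
          else f4 += size[i];
        }
        sub_sum[sub * n_obs + 3] += (double)n_chains / ncl;
        sub_sum[sub * n_obs + 4] += f1 / n_chains;
        sub_sum[sub * n_obs + 5] += f2 / n_chains;
        sub_sum[sub * n_obs + 6] += f3 / n_chains;
        sub_sum[sub * n_obs + 7] += f4 / n_chains;
        sub_nC[sub]++;
      }
      if (frame_stride > 0 && ppass % frame_stride == 0) {
        NumericMatrix fr(S.N, 3);
        for (int g = 0; g < S.N; ++g)
          for (int k = 0; k < 3; ++k) fr(g, k) = S.x[3 * g + k];
        frames.push_back(fr);
      }
    }
    if ((pass & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix sub_means(n_sub, n_obs);
  for (int s = 0; s < n_sub; ++s) {
    for (int k = 0; k < 3; ++k)
      sub_means(s, k) = sub_nE[s] > 0 ? sub_sum[s * n_obs + k] / sub_nE[s] : NA_REAL;
    for (int k = 3; k < n_obs; ++k)
      sub_means(s, k) = sub_nC[s] > 0 ? sub_sum[s * n_obs + k] / sub_nC[s] : NA_REAL;
  }
  colnames(sub_means) = CharacterVector::create(
      "energy", "rg", "ree", "n_ass", "frac1", "frac2", "frac3", "frac4p");

  bool ov2;
  double U_final = total_energy_sys(S, ov2);

  NumericMatrix final_coords(S.N, 3);
  for (int g = 0; g < S.N; ++g)
    for (int k = 0; k < 3; ++k) final_coords(g, k) = S.x[3 * g + k];

  long tot_tries = 0, tot_acc = 0;
  for (int k = 0; k < 4; ++k) { tot_tries += tries_t[k]; tot_acc += acc_t[k]; }

  return List::create(
      _["sub_means"] = sub_means,
      _["acceptance"] = (double)tot_acc / tot_tries,
      _["acceptance_by_type"] = NumericVector::create(
          _["single"] = tries_t[0] ? (double)acc_t[0] / tries_t[0] : NA_REAL,
          _["pivot"] = tries_t[1] ? (double)acc_t[1] / tries_t[1] : NA_REAL,
          _["translate"] = tries_t[2] ? (double)acc_t[2] / tries_t[2] : NA_REAL,
          _["slither"] = tries_t[3] ? (double)acc_t[3] / tries_t[3] : NA_REAL),
      _["amplitudes"] = NumericVector::create(
          _["single"] = amp_s, _["pivot"] = amp_p, _["translate"] = amp_t),
      _["frames"] = wrap(frames),
      _["final_coords"] = final_coords,
      _["energy_running"] = U,
      _["energy_final"] = U_final);
}
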