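// Analog photon Monte Carlo for a cylindrical encapsulated seed inside a
// spherical phantom, with a track-length collision-kerma estimator on
// axisymmetric (r, theta) ring cells.
//
// Geometry: silver marker rod + thin emitting coating + titanium capsule
// (cylindrical body, spherical end caps truncated by the body cylinder),
// vacuum fill gap, surrounded by a phantom sphere.  All lengths in cm,
// energies in keV, mass coefficients in cm^2/g, densities in g/cm^3.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double INF = 1e30;
static const double EPS_NUDGE = 1e-9;
static const double MEC2 = 510.99895;

enum Region { MARKER = 0, COATING = 1, WALL = 2, GAP = 3, EXTERIOR = 4 };

struct Geom {
  double r_mark, z_mark;   // marker radius / half length
  double r_coat, z_coat;   // coating outer radius / half length
  double r_in, r_out;      // capsule inner / outer cylinder radius
  double zc;               // end-cap sphere centres at z = +-zc
  double R_in, R_out;      // end-cap inner / outer sphere radius
  double r_bound;          // bounding sphere of the whole capsule
  bool   has_seed;
};

static Geom make_geom(const NumericVector& g) {
  Geom G;
  G.has_seed = g.size() > 0 && g[0] > 0;
  if (!G.has_seed) { G.r_bound = 0; return G; }
  double marker_len = g[0], marker_diam = g[1], coat = g[2];
  double cap_len = g[3], cap_od = g[4], wall = g[5], ecr = g[6];
  G.r_mark = marker_diam / 2;
  G.z_mark = marker_len / 2;
  G.r_coat = G.r_mark + coat;
  G.z_coat = G.z_mark + coat;
  G.r_out  = cap_od / 2;
  G.r_in   = G.r_out - wall;
  G.zc     = cap_len / 2 - ecr;
  G.R_out  = ecr;
  G.R_in   = ecr - wall;
  G.r_bound = std::max(G.r_out, G.zc + G.R_out) * 1.02;
  return G;
}

static inline int region_at(const Geom& G, double x, double y, double z) {
  if (!G.has_seed) return EXTERIOR;
  double s2 = x * x + y * y, az = std::fabs(z);
  if (s2 <= G.r_mark * G.r_mark && az <= G.z_mark) return MARKER;
  if (s2 <= G.r_coat * G.r_coat && az <= G.z_coat) return COATING;
  double dz = az - G.zc;
  if (s2 <= G.r_in * G.r_in &&
      (az <= G.zc || s2 + dz * dz <= G.R_in * G.R_in)) return GAP;
  if (s2 <= G.r_out * G.r_out &&
      (az <= G.zc || s2 + dz * dz <= G.R_out * G.R_out)) return WALL;
  return EXTERIOR;
}

// roots of |p + t d| crossing a cylinder of radius R about the z axis
static inline void cyl_roots(const double* p, const double* d, double R,
                             std::vector<double>& ts) {
  double a = d[0] * d[0] + d[1] * d[1];
  if (a < 1e-16) return;
  double b = p[0] * d[0] + p[1] * d[1];
  double c = p[0] * p[0] + p[1] * p[1] - R * R;
  double disc = b * b - a * c;
  if (disc <= 0) return;
  double sq = std::sqrt(disc);
  ts.push_back((-b - sq) / a);
  ts.push_back((-b + sq) / a);
}

static inline void sph_roots(const double* p, const double* d, double zc0,
                             double R, std::vector<double>& ts) {
  double pz = p[2] - zc0;
  double b = p[0] * d[0] + p[1] * d[1] + pz * d[2];
  double c = p[0] * p[0] + p[1] * p[1] + pz * pz - R * R;
  double disc = b * b - c;
  if (disc <= 0) return;
  double sq = std::sqrt(disc);
  ts.push_back(-b - sq);
  ts.push_back(-b + sq);
}

static inline void plane_roots(const double* p, const double* d, double z0,
                               std::vector<double>& ts) {
  if (std::fabs(d[2]) < 1e-16) return;
  ts.push_back((z0 - p[2]) / d[2]);
  ts.push_back((-z0 - p[2]) / d[2]);
}

// distance to next region change (midpoint classification between candidate
// surface crossings); returns length and region entered.
static double next_boundary(const Geom& G, double rph, const double* p,
                            const double* d, int cur, int* next_reg) {
  std::vector<double> ts;
  ts.reserve(32);
  if (G.has_seed) {
    cyl_roots(p, d, G.r_mark, ts);
    cyl_roots(p, d, G.r_coat, ts);
    cyl_roots(p, d, G.r_in, ts);
    cyl_roots(p, d, G.r_out, ts);
    plane_roots(p, d, G.z_mark, ts);
    plane_roots(p, d, G.z_coat, ts);
    plane_roots(p, d, G.zc, ts);
    sph_roots(p, d, G.zc, G.R_in, ts);
    sph_roots(p, d, G.zc, G.R_out, ts);
    sph_roots(p, d, -G.zc, G.R_in, ts);
    sph_roots(p, d, -G.zc, G.R_out, ts);
  }
  if (rph > 0) sph_roots(p, d, 0.0, rph, ts);
  std::vector<double> pos_ts;
  for (double t : ts) if (t > 1e-11 && t < INF) pos_ts.push_back(t);
  if (pos_ts.empty()) { *next_reg = EXTERIOR; return INF; }
  std::sort(pos_ts.begin(), pos_ts.end());
  pos_ts.push_back(pos_ts.back() + 1.0);
  double t_prev = 0.0;
  for (size_t i = 0; i + 1 < pos_ts.size(); ++i) {
    double tm = 0.5 * (pos_ts[i] + pos_ts[i + 1]);
    int reg = region_at(G, p[0] + tm * d[0], p[1] + tm * d[1], p[2] + tm * d[2]);
    bool outside = false;
    if (rph > 0) {
      double xm = p[0] + tm * d[0], ym = p[1] + tm * d[1], zm = p[2] + tm * d[2];
      outside = xm * xm + ym * ym + zm * zm > rph * rph;
    }
    if (reg != cur || outside) { *next_reg = outside ? -1 : reg; return pos_ts[i]; }
    t_prev = pos_ts[i];
  }
  (void)t_prev;
  // crosses modelled surfaces but never changes region (e.g. an exterior
  // ray grazing past the capsule with no phantom): no boundary
  *next_reg = -1;
  return INF;
}

// ------------------------------------------------------------------ tallies

struct Tally {
  int nshell;
  std::vector<double> sh_lo, sh_hi;          // disjoint, sorted
  std::vector<double> ct_edges_global;       // sorted ascending, unique
  std::vector<int> ct_off, ct_n, iv_off;     // per-shell slices
  std::vector<double> ct_edges;              // per-shell ascending edges
  std::vector<int> cell_of_interval;         // per-shell interval -> cell id
  int ncell;
  std::vector<double> sum, sum2, hbuf;
  std::vector<int> touched;
};

static Tally make_tally(const List& tl) {
  Tally T;
  T.sh_lo = as<std::vector<double> >(tl["shell_lo"]);
  T.sh_hi = as<std::vector<double> >(tl["shell_hi"]);
  T.nshell = (int)T.sh_lo.size();
  T.ct_edges_global = as<std::vector<double> >(tl["ct_edges_global"]);
  T.ct_off = as<std::vector<int> >(tl["ct_off"]);
  T.ct_n = as<std::vector<int> >(tl["ct_n"]);
  T.iv_off = as<std::vector<int> >(tl["iv_off"]);
  T.ct_edges = as<std::vector<double> >(tl["ct_edges"]);
  T.cell_of_interval = as<std::vector<int> >(tl["cell_of_interval"]);
  T.ncell = as<int>(tl["ncell"]);
  T.sum.assign(T.ncell, 0.0);
  T.sum2.assign(T.ncell, 0.0);
  T.hbuf.assign(T.ncell, 0.0);
  return T;
}

static inline int find_shell(const Tally& T, double r) {
  int lo = 0, hi = T.nshell - 1;
  while (lo <= hi) {
    int m = (lo + hi) / 2;
    if (r < T.sh_lo[m]) hi = m - 1;
    else if (r > T.sh_hi[m]) lo = m + 1;
    else return m;
  }
  return -1;
}

static inline int find_cell(const Tally& T, double r, double ct) {
  int s = find_shell(T, r);
  if (s < 0) return -1;
  const double* e = &T.ct_edges[T.ct_off[s]];
  int n = T.ct_n[s];
  if (ct < e[0] || ct > e[n - 1]) return -1;
  int lo = 0, hi = n - 2;
  while (lo < hi) {
    int m = (lo + hi + 1) / 2;
    if (ct >= e[m]) lo = m; else hi = m - 1;
  }
  return T.cell_of_interval[T.iv_off[s] + lo];
}

// cone cos(theta) = c crossings: (pz + t dz)^2 = c^2 |p + t d|^2, correct nappe
static inline void cone_roots(const double* p, const double* d, double c,
                              std::vector<double>& ts) {
  double c2 = c * c;
  double a = d[2] * d[2] - c2;                    // |d| = 1
  double b = p[2] * d[2] - c2 * (p[0] * d[0] + p[1] * d[1] + p[2] * d[2]);
  double q = p[2] * p[2] - c2 * (p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
  if (std::fabs(a) < 1e-14) {
    if (std::fabs(b) > 1e-14) {
      double t = -q / (2 * b);
      if ((p[2] + t * d[2]) * c >= 0) ts.push_back(t);
    }
    return;
  }
  double disc = b * b - a * q;
  if (disc <= 0) return;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
  if ((p[2] + t1 * d[2]) * c >= 0) ts.push_back(t1);
  if ((p[2] + t2 * d[2]) * c >= 0) ts.push_back(t2);
}

static void score_segment(Tally& T, const double* p, const double* d,
                          double len, double w) {
  if (T.ncell == 0 || len <= 0 || w <= 0) return;
  // radial range of the segment
  double pd = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
  double p2 = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
  double tstar = std::min(std::max(-pd, 0.0), len);
  double rmin = std::sqrt(std::max(0.0, p2 + 2 * tstar * pd + tstar * tstar));
  double r0 = std::sqrt(p2);
  double r1 = std::sqrt(p2 + 2 * len * pd + len * len);
  double rmax = std::max(r0, r1);
  if (rmin > T.sh_hi[T.nshell - 1] || rmax < T.sh_lo[0]) return;

  std::vector<double> ts;
  ts.reserve(64);
  ts.push_back(0.0);
  ts.push_back(len);
  for (int s = 0; s < T.nshell; ++s) {
    if (T.sh_hi[s] < rmin || T.sh_lo[s] > rmax) continue;
    sph_roots(p, d, 0.0, T.sh_lo[s], ts);
    sph_roots(p, d, 0.0, T.sh_hi[s], ts);
  }
  for (double c : T.ct_edges_global) cone_roots(p, d, c, ts);
  std::vector<double> tt;
  tt.reserve(ts.size());
  for (double t : ts) if (t >= 0 && t <= len) tt.push_back(t);
  std::sort(tt.begin(), tt.end());
  for (size_t i = 0; i + 1 < tt.size(); ++i) {
    double dl = tt[i + 1] - tt[i];
    if (dl <= 1e-13) continue;
    double tm = 0.5 * (tt[i] + tt[i + 1]);
    double x = p[0] + tm * d[0], y = p[1] + tm * d[1], z = p[2] + tm * d[2];
    double r = std::sqrt(x * x + y * y + z * z);
    if (r < 1e-12) continue;
    int cell = find_cell(T, r, z / r);
    if (cell >= 0) {
      if (T.hbuf[cell] == 0.0) T.touched.push_back(cell);
      T.hbuf[cell] += dl * w;
    }
  }
}

static inline void flush_history(Tally& T) {
  for (int c : T.touched) {
    T.sum[c] += T.hbuf[c];
    T.sum2[c] += T.hbuf[c] * T.hbuf[c];
    T.hbuf[c] = 0.0;
  }
  T.touched.clear();
}

// ---------------------------------------------------------------- materials

struct Mat {
  std::vector<double> loge, logtot, logpe, logincoh, logcoh, logmuen;
  double density, zeff;
  bool fluor;  // silver K fluorescence
};

static std::vector<Mat> make_mats(const List& lib) {
  std::vector<Mat> out;
  for (int i = 0; i < lib.size(); ++i) {
    List m = lib[i];
    Mat M;
    M.loge = as<std::vector<double> >(m["loge"]);
    M.logtot = as<std::vector<double> >(m["logtot"]);
    M.logpe = as<std::vector<double> >(m["logpe"]);
    M.logincoh = as<std::vector<double> >(m["logincoh"]);
    M.logcoh = as<std::vector<double> >(m["logcoh"]);
    std::vector<double> muen = as<std::vector<double> >(m["muen"]);
    M.logmuen.resize(muen.size());
    for (size_t k = 0; k < muen.size(); ++k) M.logmuen[k] = std::log(muen[k]);
    M.density = as<double>(m["density"]);
    M.zeff = as<double>(m["zeff"]);
    M.fluor = as<bool>(m["fluor"]);
    out.push_back(M);
  }
  return out;
}

static inline double interp1(const std::vector<double>& x,
                             const std::vector<double>& y, double xq) {
  int n = (int)x.size();
  if (xq <= x[0]) return y[0];
  if (xq >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int m = (lo + hi) / 2;
    if (x[m] <= xq) lo = m; else hi = m;
  }
  double f = (xq - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + f * (y[hi] - y[lo]);
}

static inline double mu_total(const Mat& M, double E) {
  return std::exp(interp1(M.loge, M.logtot, std::log(E)));
}
static inline double mu_pe(const Mat& M, double E) {
  return std::exp(interp1(M.loge, M.logpe, std::log(E)));
}
static inline double mu_incoh(const Mat& M, double E) {
  return std::exp(interp1(M.loge, M.logincoh, std::log(E)));
}
static inline double muen_of(const Mat& M, double E) {
  return std::exp(interp1(M.loge, M.logmuen, std::log(E)));
}

// ------------------------------------------------------------------ physics

static inline double runif1() { return unif_rand(); }

// Kahn's rejection algorithm for the Klein-Nishina distribution.
// Returns mu = cos(theta); *eratio = E'/E.
static double sample_kn(double E, double* eratio) {
  double a = E / MEC2;
  for (int it = 0; it < 10000; ++it) {
    double r1 = runif1(), r2 = runif1(), r3 = runif1();
    if (r1 <= (1 + 2 * a) / (9 + 2 * a)) {
      double x = 1 + 2 * a * r2;
      if (r3 <= 4 * (1 / x - 1 / (x * x))) {
        *eratio = 1 / x;
        return 1 + (1 - x) / a;
      }
    } else {
      double x = (1 + 2 * a) / (1 + 2 * a * r2);
      double mu = 1 + (1 - x) / a;
      if (r3 <= 0.5 * (mu * mu + 1 / x)) {
        *eratio = 1 / x;
        return mu;
      }
    }
  }
  *eratio = 1.0;
  return 1.0;
}

// Incoherent polar angle: Klein-Nishina modulated by the same screened
// incoherent scattering function S(x,Z) used for the tabulated magnitude
// (S_SCALE matches the table build), by rejection against the backscatter
// maximum.  Binding suppresses the forward angles.
static double sample_kn_binding(double E, double zeff, double* eratio) {
  double lambda = 12.39842 / E;               // Angstrom
  double xs = 0.50750 * std::cbrt(zeff);
  double xmax = 1.0 / lambda;
  double smax = 1 - 1 / std::pow(1 + (xmax / xs) * (xmax / xs), 2);
  for (int it = 0; it < 100000; ++it) {
    double mu = sample_kn(E, eratio);
    double x = std::sqrt(std::max(0.0, (1 - mu) / 2)) / lambda;
    double s = 1 - 1 / std::pow(1 + (x / xs) * (x / xs), 2);
    if (runif1() < s / smax) return mu;
  }
  return -1.0;
}

// Coherent (Rayleigh) polar angle: Thomson shape modulated by a
// Thomas-Fermi-screened form factor, by rejection.
static double sample_coherent(double E, double zeff) {
  double lambda = 12.39842 / E;               // Angstrom
  double xc = 0.35286 * std::cbrt(zeff);      // same screening as the tables
  for (int it = 0; it < 100000; ++it) {
    double ct = 2 * runif1() - 1;
    double x = std::sqrt(std::max(0.0, (1 - ct) / 2)) / lambda;
    double ff = 1 / (1 + (x / xc) * (x / xc));
    double acc = 0.5 * (1 + ct * ct) * ff * ff * ff * ff;
    if (runif1() < acc) return ct;
  }
  return 1.0;
}

static void rotate_direction(double* d, double mu, double phi) {
  double st = std::sqrt(std::max(0.0, 1 - mu * mu));
  double cp = std::cos(phi), sp = std::sin(phi);
  double u = d[0], v = d[1], w = d[2];
  double denom = std::sqrt(std::max(1e-30, 1 - w * w));
  double nu, nv, nw;
  if (denom > 1e-10) {
    nu = mu * u + st * (u * w * cp - v * sp) / denom;
    nv = mu * v + st * (v * w * cp + u * sp) / denom;
    nw = mu * w - st * denom * cp;
  } else {
    nu = st * cp;
    nv = st * sp;
    nw = (w > 0 ? mu : -mu);
  }
  double norm = std::sqrt(nu * nu + nv * nv + nw * nw);
  d[0] = nu / norm; d[1] = nv / norm; d[2] = nw / norm;
}

static void isotropic_direction(double* d) {
  double ct = 2 * runif1() - 1;
  double st = std::sqrt(std::max(0.0, 1 - ct * ct));
  double phi = 2 * M_PI * runif1();
  d[0] = st * std::cos(phi);
  d[1] = st * std::sin(phi);
  d[2] = ct;
}

// emission point uniform over the coating outer surface (lateral + end faces)
static void sample_surface_point(const Geom& G, double* p) {
  double half_len = G.z_coat;
  double a_lat = 2 * M_PI * G.r_coat * (2 * half_len);
  double a_end = M_PI * G.r_coat * G.r_coat;
  double u = runif1() * (a_lat + 2 * a_end);
  double phi = 2 * M_PI * runif1();
  if (u < a_lat) {
    p[0] = G.r_coat * std::cos(phi);
    p[1] = G.r_coat * std::sin(phi);
    p[2] = (2 * runif1() - 1) * half_len;
  } else {
    double rr = G.r_coat * std::sqrt(runif1());
    p[0] = rr * std::cos(phi);
    p[1] = rr * std::sin(phi);
    p[2] = (u < a_lat + a_end) ? half_len : -half_len;
  }
}

struct FluoPars {
  double kedge, e_ka, e_kb, p_ka, yield;  // yield = P(K shell) * omega_K
};

static FluoPars read_fluo(const List& fluo_pars) {
  FluoPars F;
  F.kedge = as<double>(fluo_pars["kedge"]);
  F.e_ka = as<double>(fluo_pars["e_ka"]);
  F.e_kb = as<double>(fluo_pars["e_kb"]);
  F.p_ka = as<double>(fluo_pars["p_ka"]);
  F.yield = as<double>(fluo_pars["yield"]);
  return F;
}

// --------------------------------------------------------------- main runs

// [[Rcpp::export]]
List cpp_run_mc(NumericVector geom, List xslib, IntegerVector region_mat,
                NumericMatrix spectrum, int n_hist, List tally_spec,
                double phantom_radius, int score_mat, double cutoff_kev,
                List fluo_pars, int source_mode) {
  Geom G = make_geom(geom);
  std::vector<Mat> mats = make_mats(xslib);
  Tally T = make_tally(tally_spec);
  FluoPars F = read_fluo(fluo_pars);

  int nline = spectrum.nrow();
  std::vector<double> cum(nline);
  double tot = 0;
  for (int i = 0; i < nline; ++i) { tot += spectrum(i, 1); cum[i] = tot; }
  for (int i = 0; i < nline; ++i) cum[i] /= tot;

  double e_emitted = 0, e_dep = 0, e_escaped = 0, e_cut = 0;
  double n_interact = 0;

  for (int h = 0; h < n_hist; ++h) {
    double p[3], d[3];
    if (source_mode == 1 || !G.has_seed) {
      p[0] = p[1] = p[2] = 0.0;
    } else {
      sample_surface_point(G, p);
    }
    isotropic_direction(d);
    double u = runif1();
    int line = 0;
    while (line < nline - 1 && u > cum[line]) ++line;
    double E = spectrum(line, 0);
    e_emitted += E;

    bool alive = true;
    for (int step = 0; step < 100000 && alive; ++step) {
      int reg = region_at(G, p[0], p[1], p[2]);
      {
        double r2 = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
        if (phantom_radius > 0 && r2 >= phantom_radius * phantom_radius) {
          e_escaped += E;
          break;
        }
      }
      int mi = region_mat[reg];
      int next_reg;
      double tb;
      if (reg == EXTERIOR) {
        // fast path: does the ray hit the capsule bounding sphere?
        bool hit_seed = false;
        if (G.has_seed) {
          double b = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
          double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] -
                     G.r_bound * G.r_bound;
          if (c < 0 || (b < 0 && b * b - c > 0)) hit_seed = true;
        }
        if (hit_seed) {
          tb = next_boundary(G, phantom_radius, p, d, reg, &next_reg);
        } else {
          double b = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
          double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] -
                     phantom_radius * phantom_radius;
          double disc = b * b - c;
          tb = disc > 0 ? (-b + std::sqrt(disc)) : INF;
          next_reg = -1;
        }
      } else {
        tb = next_boundary(G, phantom_radius, p, d, reg, &next_reg);
      }

      double s = INF;
      if (mi >= 0) {
        double mu = mu_total(mats[mi], E) * mats[mi].density;
        s = -std::log(runif1()) / mu;
      }
      double stepd = std::min(s, tb);
      if (reg == EXTERIOR && T.ncell > 0 && score_mat >= 0) {
        double w = E * muen_of(mats[score_mat], E);
        score_segment(T, p, d, std::min(stepd, tb), w);
      }
      if (s < tb) {
        // interaction
        p[0] += s * d[0]; p[1] += s * d[1]; p[2] += s * d[2];
        n_interact += 1;
        const Mat& M = mats[mi];
        double mpe = mu_pe(M, E), minc = mu_incoh(M, E), mtot = mu_total(M, E);
        double u2 = runif1() * mtot;
        if (u2 < mpe) {
          if (M.fluor && E > F.kedge && runif1() < F.yield) {
            double ef = runif1() < F.p_ka ? F.e_ka : F.e_kb;
            e_dep += E - ef;
            E = ef;
            isotropic_direction(d);
          } else {
            e_dep += E;
            alive = false;
          }
        } else if (u2 < mpe + minc) {
          double eratio;
          double mu_sc = sample_kn_binding(E, M.zeff, &eratio);
          double Enew = E * eratio;
          e_dep += E - Enew;
          rotate_direction(d, mu_sc, 2 * M_PI * runif1());
          E = Enew;
          if (E < cutoff_kev) { e_cut += E; alive = false; }
        } else {
          double mu_sc = sample_coherent(E, M.zeff);
          rotate_direction(d, mu_sc, 2 * M_PI * runif1());
        }
      } else {
        if (tb >= INF) { e_escaped += E; break; }
        double adv = tb + EPS_NUDGE;
        p[0] += adv * d[0]; p[1] += adv * d[1]; p[2] += adv * d[2];
        if (next_reg == -1) { e_escaped += E; break; }
      }
    }
    flush_history(T);
  }

  return List::create(
    _["sum"] = NumericVector(T.sum.begin(), T.sum.end()),
    _["sum2"] = NumericVector(T.sum2.begin(), T.sum2.end()),
    _["n_hist"] = n_hist,
    _["e_emitted"] = e_emitted,
    _["e_deposited"] = e_dep,
    _["e_escaped"] = e_escaped,
    _["e_cutoff"] = e_cut,
    _["n_interactions"] = n_interact);
}

// ------------------------------------------------- small exported utilities

// [[Rcpp::export]]
IntegerVector cpp_region_at(NumericVector geom, NumericMatrix pts) {
  Geom G = make_geom(geom);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = region_at(G, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
List cpp_distance_to_boundary(NumericVector geom, NumericVector origin,
                              NumericVector dir, double phantom_radius) {
  Geom G = make_geom(geom);
  double p[3] = { origin[0], origin[1], origin[2] };
  double d[3] = { dir[0], dir[1], dir[2] };
  int cur = region_at(G, p[0], p[1], p[2]);
  int next_reg;
  double t = next_boundary(G, phantom_radius, p, d, cur, &next_reg);
  return List::create(_["distance"] = t, _["region"] = cur,
                      _["next_region"] = next_reg);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_emission(NumericVector geom, NumericMatrix spectrum,
                                  int n) {
  Geom G = make_geom(geom);
  int nline = spectrum.nrow();
  std::vector<double> cum(nline);
  double tot = 0;
  for (int i = 0; i < nline; ++i) { tot += spectrum(i, 1); cum[i] = tot; }
  for (int i = 0; i < nline; ++i) cum[i] /= tot;
  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    double p[3], d[3];
    if (G.has_seed) sample_surface_point(G, p); else p[0] = p[1] = p[2] = 0;
    isotropic_direction(d);
    double u = runif1();
    int line = 0;
    while (line < nline - 1 && u > cum[line]) ++line;
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
    out(i, 3) = d[0]; out(i, 4) = d[1]; out(i, 5) = d[2];
    out(i, 6) = spectrum(line, 0);
  }
  return out;
}

// Track a single photon; returns segments (x0,y0,z0,x1,y1,z1,energy,region)
// and the terminal fate (0 absorbed, 1 escaped phantom, 2 cutoff).
// [[Rcpp::export]]
List cpp_track_photon(NumericVector geom, List xslib, IntegerVector region_mat,
                      NumericVector origin, NumericVector dir, double energy,
                      double phantom_radius, double cutoff_kev,
                      List fluo_pars) {
  Geom G = make_geom(geom);
  std::vector<Mat> mats = make_mats(xslib);
  FluoPars F = read_fluo(fluo_pars);
  double p[3] = { origin[0], origin[1], origin[2] };
  double d[3] = { dir[0], dir[1], dir[2] };
  double dn = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (dn < 1e-12) stop("zero-length direction");
  d[0] /= dn; d[1] /= dn; d[2] /= dn;
  double E = energy;
  int fate = 1;
  std::vector<double> segs;
  bool alive = true;
  for (int step = 0; step < 100000 && alive; ++step) {
    double r2 = p[0]*p[0] + p[1]*p[1] + p[2]*p[2];
    if (phantom_radius > 0 && r2 >= phantom_radius * phantom_radius) {
      fate = 1; break;
    }
    int reg = region_at(G, p[0], p[1], p[2]);
    int mi = region_mat[reg];
    int next_reg;
    double tb = next_boundary(G, phantom_radius, p, d, reg, &next_reg);
    double s = INF;
    if (mi >= 0) {
      double mu = mu_total(mats[mi], E) * mats[mi].density;
      s = -std::log(runif1()) / mu;
    }
    double stepd = std::min(s, tb);
    if (stepd >= INF) { fate = 1; break; }
    double q[3] = { p[0] + stepd * d[0], p[1] + stepd * d[1],
                    p[2] + stepd * d[2] };
    segs.push_back(p[0]); segs.push_back(p[1]); segs.push_back(p[2]);
    segs.push_back(q[0]); segs.push_back(q[1]); segs.push_back(q[2]);
    segs.push_back(E); segs.push_back(reg);
    if (s < tb) {
      p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
      const Mat& M = mats[mi];
      double mpe = mu_pe(M, E), minc = mu_incoh(M, E), mtot = mu_total(M, E);
      double u2 = runif1() * mtot;
      if (u2 < mpe) {
        if (M.fluor && E > F.kedge && runif1() < F.yield) {
          E = runif1() < F.p_ka ? F.e_ka : F.e_kb;
          isotropic_direction(d);
        } else { fate = 0; alive = false; }
      } else if (u2 < mpe + minc) {
        double eratio;
        double mu_sc = sample_kn_binding(E, M.zeff, &eratio);
        rotate_direction(d, mu_sc, 2 * M_PI * runif1());
        E *= eratio;
        if (E < cutoff_kev) { fate = 2; alive = false; }
      } else {
        double mu_sc = sample_coherent(E, M.zeff);
        rotate_direction(d, mu_sc, 2 * M_PI * runif1());
      }
    } else {
      double adv = tb + EPS_NUDGE;
      p[0] += adv * d[0]; p[1] += adv * d[1]; p[2] += adv * d[2];
      if (next_reg == -1) { fate = 1; break; }
    }
  }
  int nseg = (int)segs.size() / 8;
  NumericMatrix m(nseg, 8);
  for (int i = 0; i < nseg; ++i)
    for (int j = 0; j < 8; ++j) m(i, j) = segs[i * 8 + j];
  colnames(m) = CharacterVector::create("x0", "y0", "z0", "x1", "y1", "z1",
                                        "energy_kev", "region");
  return List::create(_["segments"] = m, _["fate"] = fate,
                      _["final_energy"] = E);
}

// zeff <= 0 samples the free-electron Klein-Nishina distribution; a
// positive zeff applies the screened incoherent-scattering-function
// rejection used in transport.
// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy, int n, double zeff = -1.0) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double eratio;
    double mu = zeff > 0 ? sample_kn_binding(energy, zeff, &eratio)
                         : sample_kn(energy, &eratio);
    out(i, 0) = mu;
    out(i, 1) = eratio;
  }
  return out;
}
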