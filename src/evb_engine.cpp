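// Two-state EVB engine: diabatic force-field evaluation with per-term
// rr/rs/ss breakdowns, BAOAB Langevin sampling on lambda-mapping potentials,
// and a 1D engine for analytically tractable oracle systems.
//
// Units: kcal/mol, Angstrom, amu, fs at the interface. Internally time is in
// AKMA-like units (1 internal unit = 48.88821 fs) so that kinetic energy
// 0.5*m*v^2 comes out in kcal/mol directly.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double COULOMB = 332.0636;      // kcal*A/(mol*e^2)
static const double KBOLTZ  = 0.0019872041;  // kcal/(mol*K)
static const double TIMEU   = 48.88821;      // fs per internal time unit

// ---------------------------------------------------------------------------
// deterministic RNG (Box-Muller on top of mt19937_64; avoids the
// implementation-defined std::normal_distribution)
struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {
    // (0,1]
    return (static_cast<double>(eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// force-field containers

struct MorseB { int i, j; double D, a, r0; };
struct Ang    { int i, j, k; double kth, th0; };
struct Tor    { int i, j, k, l; double kphi; int n; double delta; };
struct Imp    { int i, j, k, l; double kxi, xi0; };

struct StateFF {
  std::vector<MorseB> bonds;
  std::vector<Ang> angles;
  std::vector<Tor> torsions;
  std::vector<Imp> impropers;
  std::vector<double> q, sig, eps;
  // pair kind per (i<j): 0 = full, 1 = excluded, 2 = 1-4 (scaled 0.5)
  std::vector<signed char> pair_kind;
};

struct SystemFF {
  int n = 0;
  std::vector<double> mass;
  std::vector<char> reacting;
  StateFF st[2];
  double dalpha = 0.0, H12 = 0.0;
  // flat-bottom spherical restraint (all atoms) + per-atom position restraints
  bool has_sphere = false;
  double cx = 0, cy = 0, cz = 0, radius = 0, ksph = 0;
  std::vector<int> pr_idx;
  std::vector<double> pr_k, pr_ref; // pr_ref: 3 per restrained atom
};

// term indices in the 3x6 breakdown (rows rr/rs/ss)
enum { T_BOND = 0, T_ANGLE, T_TORS, T_IMPR, T_ELEC, T_VDW, NTERM };

static int bonded_group(const std::vector<char>& reacting, const int* ids, int k) {
  int nr = 0;
  for (int a = 0; a < k; ++a) nr += reacting[ids[a]] ? 1 : 0;
  if (nr == k) return 0;
  if (nr == 0) return 2;
  return 1;
}

static void parse_state(const List& s, int n, StateFF& out) {
  DataFrame bonds = as<DataFrame>(s["bonds"]);
  {
    IntegerVector bi = bonds["i"], bj = bonds["j"];
    NumericVector D = bonds["D"], a = bonds["a"], r0 = bonds["r0"];
    for (int t = 0; t < bi.size(); ++t)
      out.bonds.push_back({bi[t], bj[t], D[t], a[t], r0[t]});
  }
  DataFrame ang = as<DataFrame>(s["angles"]);
  {
    IntegerVector ai = ang["i"], aj = ang["j"], ak = ang["k"];
    NumericVector kth = ang["k_theta"], th0 = ang["theta0"];
    for (int t = 0; t < ai.size(); ++t)
      out.angles.push_back({ai[t], aj[t], ak[t], kth[t], th0[t]});
  }
  DataFrame tor = as<DataFrame>(s["torsions"]);
  {
    IntegerVector ti = tor["i"], tj = tor["j"], tk = tor["k"], tl = tor["l"],
                  tn = tor["n"];
    NumericVector kp = tor["k_phi"], dl = tor["delta"];
    for (int t = 0; t < ti.size(); ++t)
      out.torsions.push_back({ti[t], tj[t], tk[t], tl[t], kp[t], tn[t], dl[t]});
  }
  DataFrame imp = as<DataFrame>(s["impropers"]);
  {
    IntegerVector ii = imp["i"], ij = imp["j"], ik = imp["k"], il = imp["l"];
    NumericVector kx = imp["k_xi"], x0 = imp["xi0"];
    for (int t = 0; t < ii.size(); ++t)
      out.impropers.push_back({ii[t], ij[t], ik[t], il[t], kx[t], x0[t]});
  }
  out.q = as<std::vector<double>>(s["charge"]);
  out.sig = as<std::vector<double>>(s["sigma"]);
  out.eps = as<std::vector<double>>(s["epsilon"]);
  out.pair_kind.assign(static_cast<size_t>(n) * n, 0);
  DataFrame ex = as<DataFrame>(s["exclusions"]);
  {
    IntegerVector ei = ex["i"], ej = ex["j"];
    for (int t = 0; t < ei.size(); ++t) {
      out.pair_kind[static_cast<size_t>(ei[t]) * n + ej[t]] = 1;
      out.pair_kind[static_cast<size_t>(ej[t]) * n + ei[t]] = 1;
    }
  }
  DataFrame p14 = as<DataFrame>(s["pairs14"]);
  {
    IntegerVector pi = p14["i"], pj = p14["j"];
    for (int t = 0; t < pi.size(); ++t) {
      out.pair_kind[static_cast<size_t>(pi[t]) * n + pj[t]] = 2;
      out.pair_kind[static_cast<size_t>(pj[t]) * n + pi[t]] = 2;
    }
  }
}

static SystemFF parse_system(const List& sys) {
  SystemFF S;
  DataFrame atoms = as<DataFrame>(sys["atoms"]);
  NumericVector mass = atoms["mass"];
  LogicalVector reac = atoms["reacting"];
  S.n = mass.size();
  S.mass.assign(mass.begin(), mass.end());
  S.reacting.resize(S.n);
  for (int i = 0; i < S.n; ++i) S.reacting[i] = reac[i] ? 1 : 0;
  parse_state(as<List>(sys["state1"]), S.n, S.st[0]);
  parse_state(as<List>(sys["state2"]), S.n, S.st[1]);
  List cpl = as<List>(sys["coupling"]);
  S.dalpha = as<double>(cpl["delta_alpha"]);
  S.H12 = as<double>(cpl["H12"]);
  if (sys.containsElementNamed("restraint") && !Rf_isNull(sys["restraint"])) {
    List rs = as<List>(sys["restraint"]);
    NumericVector c = rs["center"];
    S.has_sphere = true;
    S.cx = c[0]; S.cy = c[1]; S.cz = c[2];
    S.radius = as<double>(rs["radius"]);
    S.ksph = as<double>(rs["k"]);
  }
  if (sys.containsElementNamed("posres") && !Rf_isNull(sys["posres"])) {
    DataFrame pr = as<DataFrame>(sys["posres"]);
    IntegerVector idx = pr["atom"];
    NumericVector k = pr["k"], x = pr["x"], y = pr["y"], z = pr["z"];
    for (int t = 0; t < idx.size(); ++t) {
      S.pr_idx.push_back(idx[t]);
      S.pr_k.push_back(k[t]);
      S.pr_ref.push_back(x[t]);
      S.pr_ref.push_back(y[t]);
      S.pr_ref.push_back(z[t]);
    }
  }
  return S;
}

// ---------------------------------------------------------------------------
// geometry helpers

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// dihedral angle and its gradient wrt the four atoms; returns phi in (-pi,pi]
static double dihedral(const double* ri, const double* rj, const double* rk,
                       const double* rl, double* gi, double* gj, double* gk,
                       double* gl, bool want_grad, bool* degenerate) {
  double b1[3], b2[3], b3[3];
  vsub(rj, ri, b1); vsub(rk, rj, b2); vsub(rl, rk, b3);
  double n1[3], n2[3];
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double n1n = vnorm(n1), n2n = vnorm(n2), b2n = vnorm(b2);
  if (degenerate) *degenerate = (n1n < 1e-9 || n2n < 1e-9 || b2n < 1e-12);
  if (n1n < 1e-12 || n2n < 1e-12 || b2n < 1e-12) return 0.0;
  double m[3];
  vcross(n1, n2, m);
  double phi = std::atan2(vdot(m, b2) / b2n, vdot(n1, n2));
  if (want_grad) {
    double c1 = -b2n / (n1n * n1n);
    double c2 = b2n / (n2n * n2n);
    for (int d = 0; d < 3; ++d) { gi[d] = c1 * n1[d]; gl[d] = c2 * n2[d]; }
    double s = vdot(b1, b2) / (b2n * b2n);
    double t = vdot(b3, b2) / (b2n * b2n);
    for (int d = 0; d < 3; ++d) {
      gj[d] = -(1.0 + s) * gi[d] + t * gl[d];
      gk[d] = s * gi[d] - (1.0 + t) * gl[d];
    }
  }
  return phi;
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x <= -M_PI) x += 2.0 * M_PI;
  return x;
}

// ---------------------------------------------------------------------------
// diabatic energy + forces for one state. E is a 3x6 (group x term) array in
// row-major [group*NTERM + term]; F (3n) may be null.

static void state_energy(const SystemFF& S, int which, const double* x,
                         double* E, double* F) {
  const StateFF& ff = S.st[which];
  const int n = S.n;
  std::fill(E, E + 3 * NTERM, 0.0);

  for (const MorseB& b : ff.bonds) {
    const double* ri = x + 3 * b.i;
    const double* rj = x + 3 * b.j;
    double d[3]; vsub(ri, rj, d);
    double r = vnorm(d);
    if (r < 1e-6) stop("overlapping atoms in bond (%d,%d)", b.i, b.j);
    double ex = std::exp(-b.a * (r - b.r0));
    double om = 1.0 - ex;
    int ids[2] = {b.i, b.j};
    E[bonded_group(S.reacting, ids, 2) * NTERM + T_BOND] += b.D * om * om;
    if (F) {
      double dVdr = 2.0 * b.D * om * b.a * ex;
      for (int dd = 0; dd < 3; ++dd) {
        double f = -dVdr * d[dd] / r;
        F[3 * b.i + dd] += f;
        F[3 * b.j + dd] -= f;
      }
    }
  }

  for (const Ang& a : ff.angles) {
    const double* ri = x + 3 * a.i;
    const double* rj = x + 3 * a.j;
    const double* rk = x + 3 * a.k;
    double u[3], v[3];
    vsub(ri, rj, u); vsub(rk, rj, v);
    double un = vnorm(u), vn = vnorm(v);
    if (un < 1e-9 || vn < 1e-9) stop("degenerate angle (%d,%d,%d)", a.i, a.j, a.k);
    double ct = vdot(u, v) / (un * vn);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - a.th0;
    int ids[3] = {a.i, a.j, a.k};
    E[bonded_group(S.reacting, ids, 3) * NTERM + T_ANGLE] += 0.5 * a.kth * dth * dth;
    if (F) {
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      double dVdth = a.kth * dth;
      for (int dd = 0; dd < 3; ++dd) {
        double dthdri = (ct * u[dd] / un - v[dd] / vn) / (un * st);
        double dthdrk = (ct * v[dd] / vn - u[dd] / un) / (vn * st);
        F[3 * a.i + dd] -= dVdth * dthdri;
        F[3 * a.k + dd] -= dVdth * dthdrk;
        F[3 * a.j + dd] += dVdth * (dthdri + dthdrk);
      }
    }
  }

  for (const Tor& t : ff.torsions) {
    double gi[3], gj[3], gk[3], gl[3];
    bool degen = false;
    double phi = dihedral(x + 3 * t.i, x + 3 * t.j, x + 3 * t.k, x + 3 * t.l,
                          gi, gj, gk, gl, F != nullptr, &degen);
    if (degen) continue; // collinear: torsion undefined, zero contribution
    int ids[4] = {t.i, t.j, t.k, t.l};
    E[bonded_group(S.reacting, ids, 4) * NTERM + T_TORS] +=
        t.kphi * (1.0 + std::cos(t.n * phi - t.delta));
    if (F) {
      double dVdphi = -t.kphi * t.n * std::sin(t.n * phi - t.delta);
      for (int dd = 0; dd < 3; ++dd) {
        F[3 * t.i + dd] -= dVdphi * gi[dd];
        F[3 * t.j + dd] -= dVdphi * gj[dd];
        F[3 * t.k + dd] -= dVdphi * gk[dd];
        F[3 * t.l + dd] -= dVdphi * gl[dd];
      }
    }
  }

  for (const Imp& im : ff.impropers) {
    double gi[3], gj[3], gk[3], gl[3];
    bool degen = false;
    double xi = dihedral(x + 3 * im.i, x + 3 * im.j, x + 3 * im.k, x + 3 * im.l,
                         gi, gj, gk, gl, F != nullptr, &degen);
    if (degen) continue;
    double dxi = wrap_pi(xi - im.xi0);
    int ids[4] = {im.i, im.j, im.k, im.l};
    E[bonded_group(S.reacting, ids, 4) * NTERM + T_IMPR] += 0.5 * im.kxi * dxi * dxi;
    if (F) {
      double dVdxi = im.kxi * dxi;
      for (int dd = 0; dd < 3; ++dd) {
        F[3 * im.i + dd] -= dVdxi * gi[dd];
        F[3 * im.j + dd] -= dVdxi * gj[dd];
        F[3 * im.k + dd] -= dVdxi * gk[dd];
        F[3 * im.l + dd] -= dVdxi * gl[dd];
      }
    }
  }

  // nonbonded: no cutoff, geometric-mean LJ combination, 1-4 scaled by 0.5
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      signed char kind = ff.pair_kind[static_cast<size_t>(i) * n + j];
      if (kind == 1) continue;
      double scale = (kind == 2) ? 0.5 : 1.0;
      double d[3];
      vsub(x + 3 * i, x + 3 * j, d);
      double r2 = vdot(d, d);
      double r = std::sqrt(r2);
      if (r < 1e-6) stop("overlapping atoms (%d,%d)", i, j);
      int grp = (S.reacting[i] ? 1 : 0) + (S.reacting[j] ? 1 : 0);
      int g = (grp == 2) ? 0 : (grp == 1 ? 1 : 2);
      double qq = ff.q[i] * ff.q[j];
      double e_el = 0.0, dVdr_el = 0.0;
      if (qq != 0.0) {
        e_el = scale * COULOMB * qq / r;
        dVdr_el = -e_el / r;
      }
      double e_vdw = 0.0, dVdr_vdw = 0.0;
      double epsij = std::sqrt(ff.eps[i] * ff.eps[j]);
      if (epsij > 0.0) {
        double sij = std::sqrt(ff.sig[i] * ff.sig[j]);
        double sr2 = sij * sij / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        e_vdw = scale * 4.0 * epsij * (sr12 - sr6);
        dVdr_vdw = scale * 4.0 * epsij * (-12.0 * sr12 + 6.0 * sr6) / r;
      }
      E[g * NTERM + T_ELEC] += e_el;
      E[g * NTERM + T_VDW] += e_vdw;
      if (F) {
        double dVdr = dVdr_el + dVdr_vdw;
        for (int dd = 0; dd < 3; ++dd) {
          double f = -dVdr * d[dd] / r;
          F[3 * i + dd] += f;
          F[3 * j + dd] -= f;
        }
      }
    }
  }
}

static double restraint_energy(const SystemFF& S, const double* x, double* F) {
  double E = 0.0;
  if (S.has_sphere) {
    for (int i = 0; i < S.n; ++i) {
      double d[3] = {x[3 * i] - S.cx, x[3 * i + 1] - S.cy, x[3 * i + 2] - S.cz};
      double r = vnorm(d);
      if (r > S.radius) {
        double dr = r - S.radius;
        E += 0.5 * S.ksph * dr * dr;
        if (F) {
          for (int dd = 0; dd < 3; ++dd)
            F[3 * i + dd] -= S.ksph * dr * d[dd] / r;
        }
      }
    }
  }
  for (size_t t = 0; t < S.pr_idx.size(); ++t) {
    int i = S.pr_idx[t];
    double d[3] = {x[3 * i] - S.pr_ref[3 * t], x[3 * i + 1] - S.pr_ref[3 * t + 1],
                   x[3 * i + 2] - S.pr_ref[3 * t + 2]};
    E += 0.5 * S.pr_k[t] * vdot(d, d);
    if (F) {
      for (int dd = 0; dd < 3; ++dd) F[3 * i + dd] -= S.pr_k[t] * d[dd];
    }
  }
  return E;
}

static inline double esum(const double* E) {
  double s = 0.0;
  for (int i = 0; i < 3 * NTERM; ++i) s += E[i];
  return s;
}

static inline void ground_state(double e1, double e2s, double H12, double* Eg,
                                double* w1, double* w2) {
  double d = e1 - e2s;
  double rad = std::sqrt(d * d + 4.0 * H12 * H12);
  *Eg = 0.5 * (e1 + e2s) - 0.5 * rad;
  if (H12 == 0.0) {
    *w1 = (e1 <= e2s) ? 1.0 : 0.0;
    *w2 = 1.0 - *w1;
  } else {
    double t = (*Eg - e1) / H12; // c2/c1
    double t2 = t * t;
    *w1 = 1.0 / (1.0 + t2);
    *w2 = t2 / (1.0 + t2);
  }
}

// ---------------------------------------------------------------------------
// exported evaluators

// [[Rcpp::export]]
List cpp_diabatic_energy(List sys, NumericMatrix coords, int state) {
  SystemFF S = parse_system(sys);
  if (coords.nrow() != S.n || coords.ncol() != 3)
    stop("coordinate matrix must be n_atoms x 3");
  std::vector<double> x(coords.begin(), coords.end());
  // coords come in column-major; repack row-major (x,y,z per atom)
  std::vector<double> xr(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) xr[3 * i + d] = coords(i, d);
  double E[3 * NTERM];
  state_energy(S, state - 1, xr.data(), E, nullptr);
  NumericMatrix out(3, NTERM);
  for (int g = 0; g < 3; ++g)
    for (int t = 0; t < NTERM; ++t) out(g, t) = E[g * NTERM + t];
  out.attr("dimnames") = List::create(
      CharacterVector::create("rr", "rs", "ss"),
      CharacterVector::create("bond", "angle", "torsion", "improper", "elec", "vdw"));
  return List::create(_["terms"] = out, _["total"] = esum(E));
}

// [[Rcpp::export]]
NumericMatrix cpp_diabatic_forces(List sys, NumericMatrix coords, int state) {
  SystemFF S = parse_system(sys);
  std::vector<double> xr(3 * S.n), F(3 * S.n, 0.0);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) xr[3 * i + d] = coords(i, d);
  double E[3 * NTERM];
  state_energy(S, state - 1, xr.data(), E, F.data());
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = F[3 * i + d];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_maxwell_velocities(NumericVector mass, double T, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  int n = mass.size();
  NumericMatrix v(n, 3);
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(KBOLTZ * T / mass[i]);
    for (int d = 0; d < 3; ++d) v(i, d) = s * rng.gauss();
  }
  return v;
}

// [[Rcpp::export]]
List cpp_run_window3d(List sys, NumericMatrix coords0, NumericMatrix vel0,
                      double lambda, double T, double dt_fs, double gamma_ps,
                      int n_steps, int stride, double seed,
                      bool record_breakdowns, bool record_coords) {
  SystemFF S = parse_system(sys);
  const int n = S.n;
  if (coords0.nrow() != n) stop("coordinate matrix must be n_atoms x 3");
  std::vector<double> x(3 * n), v(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = coords0(i, d);
      v[3 * i + d] = vel0(i, d);
    }
  Rng rng(static_cast<uint64_t>(seed));
  const double dt = dt_fs / TIMEU;
  const double gam = gamma_ps * TIMEU / 1000.0;
  const double c1 = std::exp(-gam * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const int ndof = 3 * n;

  std::vector<double> E1(3 * NTERM), E2(3 * NTERM);
  std::vector<double> F1(3 * n), F2(3 * n), F(3 * n);

  auto eval_forces = [&]() {
    std::fill(F1.begin(), F1.end(), 0.0);
    std::fill(F2.begin(), F2.end(), 0.0);
    state_energy(S, 0, x.data(), E1.data(), F1.data());
    state_energy(S, 1, x.data(), E2.data(), F2.data());
    for (int k = 0; k < 3 * n; ++k)
      F[k] = (1.0 - lambda) * F1[k] + lambda * F2[k];
    return restraint_energy(S, x.data(), F.data());
  };

  double e_restr = eval_forces();
  int nf = n_steps / stride;
  NumericMatrix frames(nf, 8);
  colnames(frames) = CharacterVector::create("step", "eps1", "eps2s", "Eg",
                                             "eps_m", "ekin", "kinT", "e_restraint");
  NumericMatrix bk1, bk2;
  NumericVector crd;
  if (record_breakdowns) { bk1 = NumericMatrix(nf, 18); bk2 = NumericMatrix(nf, 18); }
  if (record_coords) crd = NumericVector(static_cast<R_xlen_t>(nf) * 3 * n);

  int fi = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB
    for (int i = 0; i < n; ++i) {
      double invm = 1.0 / S.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += 0.5 * dt * F[3 * i + d] * invm;
    }
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(KBOLTZ * T / S.mass[i]);
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * s * rng.gauss();
    }
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    e_restr = eval_forces();
    for (int i = 0; i < n; ++i) {
      double invm = 1.0 / S.mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += 0.5 * dt * F[3 * i + d] * invm;
    }
    if (!std::isfinite(F[0]) || !std::isfinite(x[0]))
      stop("integration blow-up at step %d", step);

    if (step % stride == 0) {
      double e1 = esum(E1.data());
      double e2s = esum(E2.data()) + S.dalpha;
      double Eg, w1, w2;
      ground_state(e1, e2s, S.H12, &Eg, &w1, &w2);
      double ekin = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          ekin += 0.5 * S.mass[i] * v[3 * i + d] * v[3 * i + d];
      frames(fi, 0) = step;
      frames(fi, 1) = e1;
      frames(fi, 2) = e2s;
      frames(fi, 3) = Eg;
      frames(fi, 4) = (1.0 - lambda) * e1 + lambda * e2s;
      frames(fi, 5) = ekin;
      frames(fi, 6) = 2.0 * ekin / (ndof * KBOLTZ);
      frames(fi, 7) = e_restr;
      if (record_breakdowns) {
        for (int k = 0; k < 18; ++k) { bk1(fi, k) = E1[k]; bk2(fi, k) = E2[k]; }
      }
      if (record_coords) {
        for (int k = 0; k < 3 * n; ++k)
          crd[static_cast<R_xlen_t>(fi) * 3 * n + k] = x[k];
      }
      ++fi;
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { xf(i, d) = x[3 * i + d]; vf(i, d) = v[3 * i + d]; }
  List out = List::create(_["frames"] = frames, _["coords"] = R_NilValue,
                          _["breakdown1"] = R_NilValue, _["breakdown2"] = R_NilValue,
                          _["final_coords"] = xf, _["final_vel"] = vf);
  if (record_breakdowns) { out["breakdown1"] = bk1; out["breakdown2"] = bk2; }
  if (record_coords) { crd.attr("dim") = IntegerVector::create(3 * n, nf); out["coords"] = crd; }
  return out;
}

// ---------------------------------------------------------------------------
// 1D oracle engine. Diabat coded as numeric vector:
//   c(0, k, x0, offset)    harmonic: 0.5*k*(x-x0)^2 + offset
//   c(1, D, a, x0, offset) Morse:    D*(1-exp(-a*(x-x0)))^2 + offset

static inline double pot1d(const NumericVector& p, double x, double* dVdx) {
  if (p[0] == 0.0) {
    double d = x - p[2];
    if (dVdx) *dVdx = p[1] * d;
    return 0.5 * p[1] * d * d + p[3];
  }
  double ex = std::exp(-p[2] * (x - p[3]));
  double om = 1.0 - ex;
  if (dVdx) *dVdx = 2.0 * p[1] * om * p[2] * ex;
  return p[1] * om * om + p[4];
}

// [[Rcpp::export]]
NumericVector cpp_pot1d(NumericVector p, NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = pot1d(p, x[i], nullptr);
  return out;
}

// [[Rcpp::export]]
List cpp_run_window1d(NumericVector d1, NumericVector d2, double dalpha,
                      double H12, double lambda, double T, double dt_fs,
                      double gamma_ps, int n_steps, int stride, double seed,
                      double x0, double v0, double mass) {
  Rng rng(static_cast<uint64_t>(seed));
  const double dt = dt_fs / TIMEU;
  const double gam = gamma_ps * TIMEU / 1000.0;
  const double c1 = std::exp(-gam * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double sig = std::sqrt(KBOLTZ * T / mass);
  double x = x0, v = v0;
  double g1, g2;
  double e1 = pot1d(d1, x, &g1);
  double e2 = pot1d(d2, x, &g2);
  double Fm = -((1.0 - lambda) * g1 + lambda * g2);
  int nf = n_steps / stride;
  NumericMatrix frames(nf, 8);
  colnames(frames) = CharacterVector::create("step", "x", "eps1", "eps2s", "Eg",
                                             "eps_m", "ekin", "kinT");
  int fi = 0;
  for (int step = 1; step <= n_steps; ++step) {
    v += 0.5 * dt * Fm / mass;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * sig * rng.gauss();
    x += 0.5 * dt * v;
    e1 = pot1d(d1, x, &g1);
    e2 = pot1d(d2, x, &g2);
    Fm = -((1.0 - lambda) * g1 + lambda * g2);
    v += 0.5 * dt * Fm / mass;
    if (!std::isfinite(x)) stop("integration blow-up at step %d", step);
    if (step % stride == 0) {
      double e2s = e2 + dalpha;
      double Eg, w1, w2;
      ground_state(e1, e2s, H12, &Eg, &w1, &w2);
      double ekin = 0.5 * mass * v * v;
      frames(fi, 0) = step;
      frames(fi, 1) = x;
      frames(fi, 2) = e1;
      frames(fi, 3) = e2s;
      frames(fi, 4) = Eg;
      frames(fi, 5) = (1.0 - lambda) * e1 + lambda * e2s;
      frames(fi, 6) = ekin;
      frames(fi, 7) = 2.0 * ekin / KBOLTZ;
      ++fi;
    }
  }
  return List::create(_["frames"] = frames, _["final_x"] = x, _["final_v"] = v);
}
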