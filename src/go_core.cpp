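// Compiled core: single-well Go energy/forces, exponential double-well
// mixing, and the BAOAB Langevin integrator. Internal units: kcal/mol,
// Angstrom, g/mol; internal time unit sqrt(g/mol A^2 / (kcal/mol)).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Pot {
  int n;
  std::vector<double> bond_r0;
  double bond_k;
  double th1, th2, sig, eps_a;
  std::vector<double> dih_phi0, dih_k;
  std::vector<int> ci, cj;
  std::vector<double> cr0, ceps;
  double rep_eps, rep_sigma;
  int min_sep;
  std::vector<char> is_native; // n*n lookup
};

static Pot parse_pot(List p) {
  Pot q;
  q.n = as<int>(p["n"]);
  q.bond_r0 = as<std::vector<double> >(p["bond_r0"]);
  q.bond_k = as<double>(p["bond_k"]);
  q.th1 = as<double>(p["th1"]); q.th2 = as<double>(p["th2"]);
  q.sig = as<double>(p["sig"]); q.eps_a = as<double>(p["eps_a"]);
  q.dih_phi0 = as<std::vector<double> >(p["dih_phi0"]);
  q.dih_k = as<std::vector<double> >(p["dih_k"]);
  q.ci = as<std::vector<int> >(p["ci"]);
  q.cj = as<std::vector<int> >(p["cj"]);
  q.cr0 = as<std::vector<double> >(p["cr0"]);
  q.ceps = as<std::vector<double> >(p["ceps"]);
  q.rep_eps = as<double>(p["rep_eps"]);
  q.rep_sigma = as<double>(p["rep_sigma"]);
  q.min_sep = as<int>(p["min_sep"]);
  q.is_native.assign((size_t)q.n * q.n, 0);
  for (size_t k = 0; k < q.ci.size(); ++k) {
    int i = q.ci[k] - 1, j = q.cj[k] - 1;
    q.is_native[(size_t)i * q.n + j] = 1;
    q.is_native[(size_t)j * q.n + i] = 1;
  }
  return q;
}

struct Terms { double bond, angle, dihedral, contact, repulsion; };

// Energy and forces (f accumulated as -dV/dx, caller zeroes).
static double eforce(const Pot& p, const double* x, double* f, Terms* tm) {
  const int n = p.n;
  double Eb = 0, Ea = 0, Ed = 0, Ec = 0, Er = 0;
  // bonds
  for (int k = 0; k < n - 1; ++k) {
    double dx[3], r2 = 0;
    for (int d = 0; d < 3; ++d) { dx[d] = x[3*(k+1)+d] - x[3*k+d]; r2 += dx[d]*dx[d]; }
    double r = std::sqrt(r2);
    double dr = r - p.bond_r0[k];
    Eb += 0.5 * p.bond_k * dr * dr;
    double g = p.bond_k * dr / r; // dV/dr / r
    for (int d = 0; d < 3; ++d) {
      f[3*k+d]     += g * dx[d];
      f[3*(k+1)+d] -= g * dx[d];
    }
  }
  // generic double-basin angles
  const double inv2s2 = 1.0 / (2.0 * p.sig * p.sig);
  for (int k = 0; k < n - 2; ++k) {
    const double *a = x + 3*k, *b = x + 3*(k+1), *c = x + 3*(k+2);
    double u[3], v[3], lu2 = 0, lv2 = 0, dot = 0;
    for (int d = 0; d < 3; ++d) {
      u[d] = a[d] - b[d]; v[d] = c[d] - b[d];
      lu2 += u[d]*u[d]; lv2 += v[d]*v[d]; dot += u[d]*v[d];
    }
    double lu = std::sqrt(lu2), lv = std::sqrt(lv2);
    double ct = dot / (lu * lv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double g1 = std::exp(-(th - p.th1) * (th - p.th1) * inv2s2);
    double g2 = std::exp(-(th - p.th2) * (th - p.th2) * inv2s2);
    double s = g1 + g2 + 1e-300;
    Ea += -p.eps_a * std::log(s);
    double dVdth = p.eps_a * (g1 * (th - p.th1) + g2 * (th - p.th2)) /
      (p.sig * p.sig * s);
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    for (int d = 0; d < 3; ++d) {
      double da = (ct * u[d] / lu - v[d] / lv) / (lu * st);
      double dc = (ct * v[d] / lv - u[d] / lu) / (lv * st);
      f[3*k+d]     -= dVdth * da;
      f[3*(k+2)+d] -= dVdth * dc;
      f[3*(k+1)+d] += dVdth * (da + dc);
    }
  }
  // dihedrals: V = k[1 - cos(dphi)] + k/2 [1 - cos(3 dphi)]
  for (int k = 0; k < n - 3; ++k) {
    const double *p1 = x + 3*k, *p2 = x + 3*(k+1), *p3 = x + 3*(k+2), *p4 = x + 3*(k+3);
    double b1[3], b2[3], b3[3];
    for (int d = 0; d < 3; ++d) {
      b1[d] = p2[d] - p1[d]; b2[d] = p3[d] - p2[d]; b3[d] = p4[d] - p3[d];
    }
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double b2l = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1sq < 1e-12 || n2sq < 1e-12 || b2l < 1e-12) continue;
    double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2], n1[0]*b2[1]-n1[1]*b2[0] };
    double xdot = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double ydot = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / b2l;
    double phi = -std::atan2(ydot, xdot);
    double dphi = phi - p.dih_phi0[k];
    double kd = p.dih_k[k];
    Ed += kd * (1.0 - std::cos(dphi)) + 0.5 * kd * (1.0 - std::cos(3.0 * dphi));
    double dVdphi = kd * std::sin(dphi) + 1.5 * kd * std::sin(3.0 * dphi);
    // dphi/dxi: F1/F4 from the normal vectors, inner atoms by the
    // lever-arm combination (verified against finite differences)
    double F1[3], F4[3];
    for (int d = 0; d < 3; ++d) {
      F1[d] = -b2l / n1sq * n1[d];
      F4[d] =  b2l / n2sq * n2[d];
    }
    double s12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (b2l*b2l);
    double s32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (b2l*b2l);
    for (int d = 0; d < 3; ++d) {
      double d1 = F1[d];
      double d2 = -(1.0 + s12) * F1[d] + s32 * F4[d];
      double d3 = s12 * F1[d] - (1.0 + s32) * F4[d];
      double d4 = F4[d];
      f[3*k+d]     -= dVdphi * d1;
      f[3*(k+1)+d] -= dVdphi * d2;
      f[3*(k+2)+d] -= dVdphi * d3;
      f[3*(k+3)+d] -= dVdphi * d4;
    }
  }
  // native contacts: 12-10-6 well, minimum -eps at r0
  for (size_t k = 0; k < p.ci.size(); ++k) {
    int i = p.ci[k] - 1, j = p.cj[k] - 1;
    double dx[3], r2 = 0;
    for (int d = 0; d < 3; ++d) { dx[d] = x[3*j+d] - x[3*i+d]; r2 += dx[d]*dx[d]; }
    double r = std::sqrt(r2);
    double xr = p.cr0[k] / r;
    double x2 = xr * xr, x6 = x2 * x2 * x2, x10 = x6 * x2 * x2, x12 = x10 * x2;
    double eps = p.ceps[k];
    Ec += eps * (13.0 * x12 - 18.0 * x10 + 4.0 * x6);
    double dVdr = -eps / r * (156.0 * x12 - 180.0 * x10 + 24.0 * x6);
    double g = dVdr / r;
    for (int d = 0; d < 3; ++d) {
      f[3*i+d] += g * dx[d];
      f[3*j+d] -= g * dx[d];
    }
  }
  // excluded volume for non-native pairs, shifted to 0 at rc = 3 sigma
  double rc = 3.0 * p.rep_sigma, rc2 = rc * rc;
  double s2 = p.rep_sigma * p.rep_sigma;
  double vshift = p.rep_eps * std::pow(1.0 / 3.0, 12);
  for (int i = 0; i < n; ++i) {
    for (int j = i + p.min_sep; j < n; ++j) {
      if (p.is_native[(size_t)i * n + j]) continue;
      double dx[3], r2 = 0;
      for (int d = 0; d < 3; ++d) { dx[d] = x[3*j+d] - x[3*i+d]; r2 += dx[d]*dx[d]; }
      if (r2 >= rc2) continue;
      double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      Er += p.rep_eps * sr12 - vshift;
      double g = -12.0 * p.rep_eps * sr12 / r2; // dV/dr / r
      for (int d = 0; d < 3; ++d) {
        f[3*i+d] += g * dx[d];
        f[3*j+d] -= g * dx[d];
      }
    }
  }
  if (tm) { tm->bond = Eb; tm->angle = Ea; tm->dihedral = Ed; tm->contact = Ec; tm->repulsion = Er; }
  return Eb + Ea + Ed + Ec + Er;
}

static void mixed_eforce(const Pot& pO, const Pot& pC, double epsO,
                         double beta, const double* x,
                         double* f, double& E, double& EO, double& EC,
                         double& wO, std::vector<double>& fO,
                         std::vector<double>& fC) {
  int m = 3 * pO.n;
  std::fill(fO.begin(), fO.end(), 0.0);
  std::fill(fC.begin(), fC.end(), 0.0);
  EO = eforce(pO, x, fO.data(), 0);
  EC = eforce(pC, x, fC.data(), 0);
  double a = -beta * (EO + epsO), b = -beta * EC;
  double mx = a > b ? a : b;
  double ea = std::exp(a - mx), eb = std::exp(b - mx);
  E = -(mx + std::log(ea + eb)) / beta;
  wO = ea / (ea + eb);
  for (int d = 0; d < m; ++d) f[d] = wO * fO[d] + (1.0 - wO) * fC[d];
}

// [[Rcpp::export]]
List cpp_single_energy(List pot, NumericMatrix xyz) {
  Pot p = parse_pot(pot);
  std::vector<double> x(3 * p.n), f(3 * p.n, 0.0);
  for (int i = 0; i < p.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = xyz(i, d);
  Terms tm;
  double E = eforce(p, x.data(), f.data(), &tm);
  return List::create(_["energy"] = E, _["forces"] = NumericVector(f.begin(), f.end()),
                      _["terms"] = List::create(_["bond"] = tm.bond,
                                                _["angle"] = tm.angle,
                                                _["dihedral"] = tm.dihedral,
                                                _["contact"] = tm.contact,
                                                _["repulsion"] = tm.repulsion));
}

// [[Rcpp::export]]
List cpp_mixed_energy(List potO, List potC, double eps_O, double beta_mix,
                      NumericMatrix xyz) {
  Pot pO = parse_pot(potO), pC = parse_pot(potC);
  int m = 3 * pO.n;
  std::vector<double> x(m), f(m), fO(m), fC(m);
  for (int i = 0; i < pO.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = xyz(i, d);
  double E, EO, EC, wO;
  mixed_eforce(pO, pC, eps_O, beta_mix, x.data(), f.data(), E, EO, EC, wO, fO, fC);
  return List::create(_["energy"] = E, _["E_O"] = EO, _["E_C"] = EC,
                      _["w_O"] = wO,
                      _["forces"] = NumericVector(f.begin(), f.end()));
}

// BAOAB Langevin integrator on the mixed (or single-well) potential.
// single_well: use only potC. Uses R's RNG (seed via set.seed in R).
// [[Rcpp::export]]
List cpp_langevin(List potO, List potC, double eps_O, double beta_mix,
                  bool single_well, NumericMatrix x0, double n_steps_d,
                  double dt, double gamma, double kBT, double mass,
                  int save_stride, double e_div) {
  Pot pC = parse_pot(potC);
  Pot pO = single_well ? pC : parse_pot(potO);
  const int n = pC.n, m = 3 * n;
  const long n_steps = (long)n_steps_d;
  std::vector<double> x(m), v(m), f(m), fO(m), fC(m);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = x0(i, d);

  RNGScope scope;
  double sd_v = std::sqrt(kBT / mass);
  for (int d = 0; d < m; ++d) v[d] = sd_v * norm_rand();

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1) * sd_v;
  const double hdtm = 0.5 * dt / mass;

  long nf = n_steps / save_stride;
  NumericVector frames((R_xlen_t)nf * n * 3);
  NumericVector Ev(nf), EOv(nf), ECv(nf);
  double E, EO, EC, wO;

  auto compute_force = [&]() {
    if (single_well) {
      std::fill(f.begin(), f.end(), 0.0);
      EC = eforce(pC, x.data(), f.data(), 0);
      E = EC; EO = NA_REAL;
    } else {
      mixed_eforce(pO, pC, eps_O, beta_mix, x.data(), f.data(), E, EO, EC, wO, fO, fC);
    }
  };
  compute_force();

  long fi = 0;
  for (long t = 1; t <= n_steps; ++t) {
    for (int d = 0; d < m; ++d) v[d] += hdtm * f[d];
    for (int d = 0; d < m; ++d) x[d] += 0.5 * dt * v[d];
    for (int d = 0; d < m; ++d) v[d] = c1 * v[d] + c2 * norm_rand();
    for (int d = 0; d < m; ++d) x[d] += 0.5 * dt * v[d];
    compute_force();
    for (int d = 0; d < m; ++d) v[d] += hdtm * f[d];
    if (!std::isfinite(E) || std::fabs(E) > e_div) {
      return List::create(_["status"] = "diverged", _["div_step"] = (double)t,
                          _["frames"] = R_NilValue);
    }
    if (t % save_stride == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[fi + nf * ((R_xlen_t)i + (R_xlen_t)n * d)] = x[3*i+d];
      Ev[fi] = E; EOv[fi] = EO; ECv[fi] = EC;
      ++fi;
    }
  }
  frames.attr("dim") = IntegerVector::create((int)nf, n, 3);
  return List::create(_["status"] = "ok", _["frames"] = frames,
                      _["E"] = Ev, _["E_O"] = EOv, _["E_C"] = ECv);
}
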