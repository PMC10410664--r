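// PC-SAFT residual Helmholtz energy, analytic derivatives, density solver.
//
// Heterosegmented (copolymer-capable) formulation: every component is a chain
// built from one or more segment types; homopolymers and small molecules are
// the one-type special case.  Association sites (donor/acceptor) live on
// segment types; cross association uses Wolbach-Sandler style combining rules.
//
// Units: T in K, number density rho in molecules/Angstrom^3, sigma in
// Angstrom, u/kB and epsHB/kB in K, pressure in Pa.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB = 1.380649e-23;           // J/K
static const double PI_ = 3.14159265358979323846;
static const double ETA_MAX = 0.7404;            // close packing bound

// Universal model constants for the dispersion integrals I1, I2
static const double AP[7][3] = {
  { 0.9105631445, -0.3084016918, -0.0906148351},
  { 0.6361281449,  0.1860531159,  0.4527842806},
  { 2.6861347891, -2.5030047259,  0.5962700728},
  {-26.547362491,  21.419793629, -1.7241829131},
  { 97.759208784, -65.255885330, -4.1302112531},
  {-159.59154087,  83.318680481,  13.776631870},
  { 91.297774084, -33.746922930, -8.6728470368}};
static const double BP[7][3] = {
  { 0.7240946941, -0.5755498075,  0.0976883116},
  { 2.2382791861,  0.6995095521, -0.2557574982},
  {-4.0025849485,  3.8925673390, -9.1558561530},
  {-21.003576815, -17.215471648,  20.642075974},
  { 26.855641363,  192.67226447, -38.804430052},
  { 206.55133841, -161.82646165,  93.626774077},
  {-355.60235612, -165.20769346, -29.666905585}};

struct Model {
  int nc, nt;
  std::vector<int> comp;                  // type -> component (0-based)
  std::vector<double> mseg, sig, u, eps, kap, nd, na;
  std::vector<double> kij;                // nc x nc, column major
  std::vector<int> b1, b2;                // bond type indices (0-based)
  std::vector<double> bfrac;              // bond fractions (sum to 1 per comp)
  std::vector<double> mcomp;              // per-component total segment number
  double kijv(int i, int j) const { return kij[i + nc * j]; }
};

static Model parse_model(const List& ml) {
  Model M;
  IntegerVector comp = ml["comp"];
  NumericVector mseg = ml["mseg"], sig = ml["sigma"], u = ml["u"],
    eps = ml["eps_hb"], kap = ml["kappa_hb"], nd = ml["n_donor"],
    na = ml["n_acceptor"], mcomp = ml["mcomp"], bfrac = ml["bond_frac"];
  IntegerVector b1 = ml["bond_t1"], b2 = ml["bond_t2"];
  NumericMatrix kij = ml["kij"];
  M.nc = kij.nrow();
  M.nt = comp.size();
  M.comp.resize(M.nt);
  for (int t = 0; t < M.nt; ++t) M.comp[t] = comp[t] - 1;
  M.mseg = as<std::vector<double> >(mseg);
  M.sig  = as<std::vector<double> >(sig);
  M.u    = as<std::vector<double> >(u);
  M.eps  = as<std::vector<double> >(eps);
  M.kap  = as<std::vector<double> >(kap);
  M.nd   = as<std::vector<double> >(nd);
  M.na   = as<std::vector<double> >(na);
  M.mcomp = as<std::vector<double> >(mcomp);
  M.kij.assign(kij.begin(), kij.end());
  M.b1.resize(b1.size());
  M.b2.resize(b2.size());
  for (int i = 0; i < b1.size(); ++i) { M.b1[i] = b1[i] - 1; M.b2[i] = b2[i] - 1; }
  M.bfrac = as<std::vector<double> >(bfrac);
  return M;
}

struct EvalOut {
  double eta, ahs, ahc, adisp, aassoc, ares;
  double dadrho, Z, p;
  std::vector<double> dadx, lnphi, XD, XA;
  bool assoc_converged;
  int assoc_iters;
};

// warm-start storage for the association solver across nearby states
struct AssocState {
  std::vector<double> XD, XA;
  bool valid = false;
};

// Full state evaluation.  When `full` is false only the density-direction
// derivative (needed for Z and p) is computed.
static EvalOut eval_state(const Model& M, double T, double rho,
                          const std::vector<double>& x, bool full,
                          AssocState* warm = NULL) {
  const int nc = M.nc, nt = M.nt;
  const int nv = full ? 1 + nc : 1;      // derivative directions: rho, x_k
  EvalOut out;
  out.assoc_converged = true;
  out.assoc_iters = 0;

  std::vector<double> d(nt);
  for (int t = 0; t < nt; ++t)
    d[t] = M.sig[t] * (1.0 - 0.12 * std::exp(-3.0 * M.u[t] / T));

  // zeta moments and their derivatives along each direction
  double zeta[4];
  std::vector<double> dz(4 * nv, 0.0);   // dz[n + 4*v]
  for (int n = 0; n < 4; ++n) {
    double s = 0.0;
    for (int t = 0; t < nt; ++t)
      s += x[M.comp[t]] * M.mseg[t] * std::pow(d[t], n);
    zeta[n] = PI_ / 6.0 * rho * s;
    dz[n + 0] = zeta[n] / rho;                       // d/drho
  }
  if (full) {
    for (int k = 0; k < nc; ++k)
      for (int n = 0; n < 4; ++n) {
        double s = 0.0;
        for (int t = 0; t < nt; ++t)
          if (M.comp[t] == k) s += M.mseg[t] * std::pow(d[t], n);
        dz[n + 4 * (1 + k)] = PI_ / 6.0 * rho * s;   // d/dx_k at fixed rho
      }
  }
  const double z0 = zeta[0], z1 = zeta[1], z2 = zeta[2], z3 = zeta[3];
  out.eta = z3;
  if (z3 >= ETA_MAX)
    stop("packing fraction eta = %f exceeds the close-packing bound", z3);

  double mbar = 0.0;
  for (int i = 0; i < nc; ++i) mbar += x[i] * M.mcomp[i];

  // ---- hard sphere -------------------------------------------------------
  const double om = 1.0 - z3;            // (1 - zeta3)
  const double lom = std::log1p(-z3);
  double ahs = (3.0 * z1 * z2 / om + z2 * z2 * z2 / (z3 * om * om) +
                (z2 * z2 * z2 / (z3 * z3) - z0) * lom) / z0;
  double dahs_dz[4];
  dahs_dz[0] = -ahs / z0 - lom / z0;
  dahs_dz[1] = 3.0 * z2 / (om * z0);
  dahs_dz[2] = (3.0 * z1 / om + 3.0 * z2 * z2 / (z3 * om * om) +
                3.0 * z2 * z2 / (z3 * z3) * lom) / z0;
  dahs_dz[3] = (3.0 * z1 * z2 / (om * om) +
                z2 * z2 * z2 * (-1.0 / (z3 * z3 * om * om) + 2.0 / (z3 * om * om * om)) -
                2.0 * z2 * z2 * z2 / (z3 * z3 * z3) * lom -
                (z2 * z2 * z2 / (z3 * z3) - z0) / om) / z0;

  std::vector<double> dahs(nv, 0.0);
  for (int v = 0; v < nv; ++v)
    for (int n = 0; n < 4; ++n) dahs[v] += dahs_dz[n] * dz[n + 4 * v];

  // radial distribution function at contact for a type pair
  auto gpair = [&](int t, int s, double& g, double& dgdz2, double& dgdz3) {
    double dts = d[t] * d[s] / (d[t] + d[s]);
    g = 1.0 / om + dts * 3.0 * z2 / (om * om) +
        dts * dts * 2.0 * z2 * z2 / (om * om * om);
    dgdz2 = 3.0 * dts / (om * om) + 4.0 * dts * dts * z2 / (om * om * om);
    dgdz3 = 1.0 / (om * om) + 6.0 * dts * z2 / (om * om * om) +
            6.0 * dts * dts * z2 * z2 / (om * om * om * om);
  };

  // ---- hard chain --------------------------------------------------------
  double ahc = mbar * ahs;
  std::vector<double> dahc(nv, 0.0);
  for (int v = 0; v < nv; ++v) dahc[v] = mbar * dahs[v];
  if (full)
    for (int k = 0; k < nc; ++k) dahc[1 + k] += M.mcomp[k] * ahs;

  const int nb = (int)M.b1.size();
  for (int b = 0; b < nb; ++b) {
    int t = M.b1[b], s = M.b2[b];
    int c = M.comp[t];
    double g, dg2, dg3;
    gpair(t, s, g, dg2, dg3);
    double w = x[c] * (M.mcomp[c] - 1.0) * M.bfrac[b];
    ahc -= w * std::log(g);
    for (int v = 0; v < nv; ++v)
      dahc[v] -= w * (dg2 * dz[2 + 4 * v] + dg3 * dz[3 + 4 * v]) / g;
    if (full)
      dahc[1 + c] -= (M.mcomp[c] - 1.0) * M.bfrac[b] * std::log(g);
  }

  // ---- dispersion --------------------------------------------------------
  // A1 = m^2 (u/kT) sigma^3, A2 = m^2 (u/kT)^2 sigma^3 (mixture averages)
  double A1 = 0.0, A2 = 0.0;
  std::vector<double> dA1x(nc, 0.0), dA2x(nc, 0.0);
  for (int t = 0; t < nt; ++t) {
    double Xt = x[M.comp[t]] * M.mseg[t];
    for (int s = 0; s < nt; ++s) {
      double Xs = x[M.comp[s]] * M.mseg[s];
      double uts = std::sqrt(M.u[t] * M.u[s]) *
                   (1.0 - M.kijv(M.comp[t], M.comp[s])) / T;
      double sts = 0.5 * (M.sig[t] + M.sig[s]);
      double s3 = sts * sts * sts;
      A1 += Xt * Xs * uts * s3;
      A2 += Xt * Xs * uts * uts * s3;
    }
  }
  if (full) {
    for (int t = 0; t < nt; ++t) {
      int ct = M.comp[t];
      for (int s = 0; s < nt; ++s) {
        double Xs = x[M.comp[s]] * M.mseg[s];
        double uts = std::sqrt(M.u[t] * M.u[s]) *
                     (1.0 - M.kijv(ct, M.comp[s])) / T;
        double sts = 0.5 * (M.sig[t] + M.sig[s]);
        double s3 = sts * sts * sts;
        dA1x[ct] += 2.0 * M.mseg[t] * Xs * uts * s3;
        dA2x[ct] += 2.0 * M.mseg[t] * Xs * uts * uts * s3;
      }
    }
  }

  const double eta = z3;
  double I1 = 0.0, I2 = 0.0, dI1e = 0.0, dI2e = 0.0, dI1m = 0.0, dI2m = 0.0;
  {
    double ei = 1.0;                      // eta^i
    double f1 = (mbar - 1.0) / mbar;
    double f2 = f1 * (mbar - 2.0) / mbar;
    double df1 = 1.0 / (mbar * mbar);
    double df2 = (3.0 * mbar - 4.0) / (mbar * mbar * mbar);
    for (int i = 0; i < 7; ++i) {
      double ai = AP[i][0] + f1 * AP[i][1] + f2 * AP[i][2];
      double bi = BP[i][0] + f1 * BP[i][1] + f2 * BP[i][2];
      I1 += ai * ei;
      I2 += bi * ei;
      if (i > 0) {
        double eim1 = std::pow(eta, i - 1);
        dI1e += ai * i * eim1;
        dI2e += bi * i * eim1;
      }
      dI1m += (df1 * AP[i][1] + df2 * AP[i][2]) * ei;
      dI2m += (df1 * BP[i][1] + df2 * BP[i][2]) * ei;
      ei *= eta;
    }
  }
  double h1 = (8.0 * eta - 2.0 * eta * eta) / std::pow(om, 4);
  double h2 = (20.0 * eta - 27.0 * eta * eta + 12.0 * std::pow(eta, 3) -
               2.0 * std::pow(eta, 4)) / std::pow(om * (2.0 - eta), 2);
  double dh1 = (-4.0 * eta * eta + 20.0 * eta + 8.0) / std::pow(om, 5);
  double dh2 = (2.0 * std::pow(eta, 3) + 12.0 * eta * eta - 48.0 * eta + 40.0) /
               std::pow(om * (2.0 - eta), 3);
  double C1 = 1.0 / (1.0 + mbar * h1 + (1.0 - mbar) * h2);
  double dC1e = -C1 * C1 * (mbar * dh1 + (1.0 - mbar) * dh2);
  double dC1m = -C1 * C1 * (h1 - h2);

  double adisp = -2.0 * PI_ * rho * I1 * A1 - PI_ * rho * mbar * C1 * I2 * A2;
  std::vector<double> dadisp(nv, 0.0);
  // d/drho at fixed x: explicit rho prefactor + eta dependence
  dadisp[0] = adisp / rho +
    (-2.0 * PI_ * rho * A1 * dI1e -
      PI_ * rho * mbar * A2 * (dC1e * I2 + C1 * dI2e)) * (eta / rho);
  if (full) {
    for (int k = 0; k < nc; ++k) {
      double de = dz[3 + 4 * (1 + k)];   // d eta / d x_k at fixed rho
      double dm = M.mcomp[k];
      dadisp[1 + k] =
        -2.0 * PI_ * rho * (I1 * dA1x[k] + A1 * (dI1e * de + dI1m * dm)) -
        PI_ * rho * (A2 * (dm * C1 * I2 +
                           mbar * (dC1e * de + dC1m * dm) * I2 +
                           mbar * C1 * (dI2e * de + dI2m * dm)) +
                     mbar * C1 * I2 * dA2x[k]);
    }
  }

  // ---- association -------------------------------------------------------
  std::vector<int> don, acc;             // site-bearing types
  for (int t = 0; t < nt; ++t) {
    if (M.nd[t] > 0) don.push_back(t);
    if (M.na[t] > 0) acc.push_back(t);
  }
  const int nD = (int)don.size(), nA = (int)acc.size();
  double aassoc = 0.0;
  std::vector<double> daassoc(nv, 0.0);
  out.XD.assign(nD, 1.0);
  out.XA.assign(nA, 1.0);

  if (nD > 0 && nA > 0) {
    // Delta matrix with contact-value derivatives
    std::vector<double> Del(nD * nA, 0.0), dDg2(nD * nA, 0.0), dDg3(nD * nA, 0.0);
    bool any = false;
    for (int a = 0; a < nD; ++a) {
      int t = don[a];
      for (int b = 0; b < nA; ++b) {
        int s = acc[b];
        double epsc = 0.5 * (M.eps[t] + M.eps[s]);
        double kapc = std::sqrt(M.kap[t] * M.kap[s]) *
          std::pow(std::sqrt(M.sig[t] * M.sig[s]) /
                   (0.5 * (M.sig[t] + M.sig[s])), 3);
        if (epsc <= 0.0 || kapc <= 0.0) continue;
        double g, dg2, dg3;
        gpair(t, s, g, dg2, dg3);
        double sts = 0.5 * (M.sig[t] + M.sig[s]);
        double pref = sts * sts * sts * kapc * std::expm1(epsc / T);
        Del[a + nD * b] = pref * g;
        dDg2[a + nD * b] = pref * dg2;
        dDg3[a + nD * b] = pref * dg3;
        any = true;
      }
    }
    if (any) {
      // damped successive substitution (Jacobi) for the site fractions
      const int maxit = 1000;
      const double tol = 1e-12, damp = 0.5;
      std::vector<double> XD(nD, 1.0), XA(nA, 1.0), XDn(nD), XAn(nA);
      if (warm && warm->valid && (int)warm->XD.size() == nD &&
          (int)warm->XA.size() == nA) {
        XD = warm->XD;
        XA = warm->XA;
      }
      int it = 0;
      for (; it < maxit; ++it) {
        double delta = 0.0;
        for (int a = 0; a < nD; ++a) {
          double ssum = 0.0;
          for (int b = 0; b < nA; ++b)
            ssum += x[M.comp[acc[b]]] * M.na[acc[b]] * XA[b] * Del[a + nD * b];
          XDn[a] = 1.0 / (1.0 + rho * ssum);
        }
        for (int b = 0; b < nA; ++b) {
          double ssum = 0.0;
          for (int a = 0; a < nD; ++a)
            ssum += x[M.comp[don[a]]] * M.nd[don[a]] * XD[a] * Del[a + nD * b];
          XAn[b] = 1.0 / (1.0 + rho * ssum);
        }
        for (int a = 0; a < nD; ++a) {
          double xn = damp * XDn[a] + (1.0 - damp) * XD[a];
          delta = std::max(delta, std::fabs(xn - XD[a]));
          XD[a] = xn;
        }
        for (int b = 0; b < nA; ++b) {
          double xn = damp * XAn[b] + (1.0 - damp) * XA[b];
          delta = std::max(delta, std::fabs(xn - XA[b]));
          XA[b] = xn;
        }
        if (delta < tol) break;
      }
      out.assoc_iters = it;
      out.assoc_converged = (it < maxit);
      out.XD = XD;
      out.XA = XA;
      if (warm) { warm->XD = XD; warm->XA = XA; warm->valid = true; }

      for (int a = 0; a < nD; ++a)
        aassoc += x[M.comp[don[a]]] * M.nd[don[a]] *
                  (std::log(XD[a]) - 0.5 * XD[a] + 0.5);
      for (int b = 0; b < nA; ++b)
        aassoc += x[M.comp[acc[b]]] * M.na[acc[b]] *
                  (std::log(XA[b]) - 0.5 * XA[b] + 0.5);

      // Derivatives via the Michelsen Q function: at the solution the site
      // fractions are stationary, so X can be held fixed.
      double Psum = 0.0;
      for (int a = 0; a < nD; ++a)
        for (int b = 0; b < nA; ++b) {
          double w = x[M.comp[don[a]]] * x[M.comp[acc[b]]] *
                     M.nd[don[a]] * M.na[acc[b]] * XD[a] * XA[b];
          Psum += w * Del[a + nD * b];
        }
      for (int v = 0; v < nv; ++v) {
        double dP = 0.0;                  // holding x weights fixed
        for (int a = 0; a < nD; ++a)
          for (int b = 0; b < nA; ++b) {
            double w = x[M.comp[don[a]]] * x[M.comp[acc[b]]] *
                       M.nd[don[a]] * M.na[acc[b]] * XD[a] * XA[b];
            dP += w * (dDg2[a + nD * b] * dz[2 + 4 * v] +
                       dDg3[a + nD * b] * dz[3 + 4 * v]);
          }
        if (v == 0) {
          daassoc[0] = -Psum - rho * dP;
        } else {
          int k = v - 1;
          double s1 = 0.0;
          for (int a = 0; a < nD; ++a)
            if (M.comp[don[a]] == k)
              s1 += M.nd[don[a]] * (std::log(XD[a]) - XD[a] + 1.0);
          for (int b = 0; b < nA; ++b)
            if (M.comp[acc[b]] == k)
              s1 += M.na[acc[b]] * (std::log(XA[b]) - XA[b] + 1.0);
          double s2 = 0.0;                // explicit x_k weights in Psum
          for (int a = 0; a < nD; ++a)
            for (int b = 0; b < nA; ++b) {
              double core = M.nd[don[a]] * M.na[acc[b]] * XD[a] * XA[b] *
                            Del[a + nD * b];
              if (M.comp[don[a]] == k) s2 += x[M.comp[acc[b]]] * core;
              if (M.comp[acc[b]] == k) s2 += x[M.comp[don[a]]] * core;
            }
          daassoc[v] = s1 - rho * (s2 + dP);
        }
      }
    }
  }

  // ---- totals ------------------------------------------------------------
  out.ahs = ahs;
  out.ahc = ahc;
  out.adisp = adisp;
  out.aassoc = aassoc;
  out.ares = ahc + adisp + aassoc;
  out.dadrho = dahc[0] + dadisp[0] + daassoc[0];
  out.Z = 1.0 + rho * out.dadrho;
  out.p = out.Z * rho * KB * T * 1e30;
  if (full) {
    out.dadx.assign(nc, 0.0);
    double xdot = 0.0;
    for (int k = 0; k < nc; ++k) {
      out.dadx[k] = dahc[1 + k] + dadisp[1 + k] + daassoc[1 + k];
      xdot += x[k] * out.dadx[k];
    }
    out.lnphi.assign(nc, 0.0);
    for (int k = 0; k < nc; ++k)
      out.lnphi[k] = out.ares + (out.Z - 1.0) + out.dadx[k] - xdot -
                     std::log(out.Z);
  }
  return out;
}

static double slit_sum_d3(const Model& M, double T, const std::vector<double>& x) {
  double s = 0.0;
  for (int t = 0; t < M.nt; ++t) {
    double d = M.sig[t] * (1.0 - 0.12 * std::exp(-3.0 * M.u[t] / T));
    s += x[M.comp[t]] * M.mseg[t] * d * d * d;
  }
  return PI_ / 6.0 * s;                   // eta = s * rho
}

// Pressure at packing fraction eta (light evaluation)
static double p_of_eta(const Model& M, double T, double eta, double s3,
                       const std::vector<double>& x, AssocState* warm) {
  double rho = eta / s3;
  EvalOut e = eval_state(M, T, rho, x, false, warm);
  return e.p;
}

// refine a bracketed pressure root with bisection + secant steps
static double refine_root(const Model& M, double T, double p, double s3,
                          const std::vector<double>& x,
                          double lo, double hi, double flo, double fhi,
                          AssocState* warm) {
  double a = lo, b = hi, fa = flo, fb = fhi;
  for (int it = 0; it < 200; ++it) {
    double mid;
    // secant proposal, fall back to bisection when outside or stagnant
    double den = fb - fa;
    if (den != 0.0) {
      mid = b - fb * (b - a) / den;
      if (!(mid > a && mid < b)) mid = 0.5 * (a + b);
    } else mid = 0.5 * (a + b);
    double fm = p_of_eta(M, T, mid, s3, x, warm) - p;
    if (std::fabs(fm) <= 1e-9 * std::fabs(p) || (b - a) < 1e-16)
      return mid;
    if ((fa < 0.0) == (fm < 0.0)) { a = mid; fa = fm; }
    else { b = mid; fb = fm; }
  }
  return 0.5 * (a + b);
}

// find density roots at given T, p.  hint: 0 = auto (lowest Gibbs),
// 1 = liquid (largest eta root), 2 = vapor (smallest eta root).
// Directional scans stop at the first bracketing interval; the auto path
// scans the whole range and compares Gibbs energies of all roots.
static double solve_eta(const Model& M, double T, double p,
                        const std::vector<double>& x, int hint) {
  double s3 = slit_sum_d3(M, T, x);
  AssocState warm;
  if (hint == 1) {
    double e_prev = ETA_MAX - 1e-5;
    double f_prev = p_of_eta(M, T, e_prev, s3, x, &warm) - p;
    const double step = 0.01;
    double ecur = e_prev;
    while (ecur > 1e-12) {
      ecur = (ecur - step > 1e-12) ? ecur - step : 1e-12;
      double f = p_of_eta(M, T, ecur, s3, x, &warm) - p;
      if ((f_prev < 0.0) != (f < 0.0))
        return refine_root(M, T, p, s3, x, ecur, e_prev, f, f_prev, &warm);
      e_prev = ecur; f_prev = f;
    }
    stop("no liquid density root found at T = %f K, p = %g Pa", T, p);
  }
  if (hint == 2) {
    std::vector<double> grid;
    for (double e = 1e-12; e < 1e-3; e *= 10.0) grid.push_back(e);
    for (double e = 1e-3; e <= ETA_MAX - 1e-4; e += 0.01) grid.push_back(e);
    double fprev = p_of_eta(M, T, grid[0], s3, x, &warm) - p;
    for (size_t i = 1; i < grid.size(); ++i) {
      double f = p_of_eta(M, T, grid[i], s3, x, &warm) - p;
      if ((fprev < 0.0) != (f < 0.0))
        return refine_root(M, T, p, s3, x, grid[i - 1], grid[i], fprev, f,
                           &warm);
      fprev = f;
    }
    stop("no vapor density root found at T = %f K, p = %g Pa", T, p);
  }
  // auto: collect all roots
  std::vector<double> grid;
  for (double e = 1e-12; e < 1e-3; e *= 10.0) grid.push_back(e);
  for (double e = 1e-3; e <= ETA_MAX - 1e-4; e += 0.0075) grid.push_back(e);
  grid.push_back(ETA_MAX - 1e-5);
  std::vector<double> roots;
  double fprev = p_of_eta(M, T, grid[0], s3, x, &warm) - p;
  for (size_t i = 1; i < grid.size(); ++i) {
    double f = p_of_eta(M, T, grid[i], s3, x, &warm) - p;
    if ((fprev < 0.0) != (f < 0.0))
      roots.push_back(refine_root(M, T, p, s3, x, grid[i - 1], grid[i],
                                  fprev, f, &warm));
    fprev = f;
  }
  if (roots.empty())
    stop("no density root found at T = %f K, p = %g Pa", T, p);
  double best = roots[0], gbest = R_PosInf;
  for (size_t i = 0; i < roots.size(); ++i) {
    double rho = roots[i] / s3;
    EvalOut e = eval_state(M, T, rho, x, false, &warm);
    double g = e.ares + (e.Z - 1.0) - std::log(e.Z);
    if (g < gbest) { gbest = g; best = roots[i]; }
  }
  return best;
}

static List eval_to_list(const EvalOut& e, double rho) {
  return List::create(
    _["rho"] = rho, _["eta"] = e.eta,
    _["a_hc"] = e.ahc, _["a_disp"] = e.adisp, _["a_assoc"] = e.aassoc,
    _["a_res"] = e.ares, _["a_hs"] = e.ahs,
    _["Z"] = e.Z, _["p"] = e.p,
    _["dadx"] = wrap(e.dadx), _["lnphi"] = wrap(e.lnphi),
    _["XD"] = wrap(e.XD), _["XA"] = wrap(e.XA),
    _["assoc_converged"] = e.assoc_converged,
    _["assoc_iters"] = e.assoc_iters);
}

// [[Rcpp::export]]
List cpp_eval(List model, double T, double rho, NumericVector x, bool full) {
  Model M = parse_model(model);
  std::vector<double> xv = as<std::vector<double> >(x);
  EvalOut e = eval_state(M, T, rho, xv, full);
  if (!e.assoc_converged)
    warning("association site-fraction solver did not reach 1e-12 in 1000 iterations");
  return eval_to_list(e, rho);
}

// [[Rcpp::export]]
List cpp_density(List model, double T, double p, NumericVector x, int hint) {
  Model M = parse_model(model);
  std::vector<double> xv = as<std::vector<double> >(x);
  double s3 = slit_sum_d3(M, T, xv);
  double eta = solve_eta(M, T, p, xv, hint);
  return List::create(_["eta"] = eta, _["rho"] = eta / s3);
}

// [[Rcpp::export]]
List cpp_state_tp(List model, double T, double p, NumericVector x, int hint) {
  Model M = parse_model(model);
  std::vector<double> xv = as<std::vector<double> >(x);
  double s3 = slit_sum_d3(M, T, xv);
  double eta = solve_eta(M, T, p, xv, hint);
  EvalOut e = eval_state(M, T, eta / s3, xv, true);
  return eval_to_list(e, eta / s3);
}

// Fugacity coefficient logs over a grid of binary compositions plus the two
// pure liquids; used by the phase-equilibrium layer to build activity and
// Gibbs-of-mixing curves in one call.
// [[Rcpp::export]]
List cpp_lnphi_grid(List model, double T, double p, NumericMatrix xmat,
                    int hint) {
  Model M = parse_model(model);
  int n = xmat.nrow(), nc = xmat.ncol();
  NumericMatrix lnphi(n, nc);
  NumericVector Z(n), rho(n);
  for (int r = 0; r < n; ++r) {
    std::vector<double> xv(nc);
    for (int k = 0; k < nc; ++k) xv[k] = xmat(r, k);
    double s3 = slit_sum_d3(M, T, xv);
    double eta = solve_eta(M, T, p, xv, hint);
    EvalOut e = eval_state(M, T, eta / s3, xv, true);
    for (int k = 0; k < nc; ++k) lnphi(r, k) = e.lnphi[k];
    Z[r] = e.Z;
    rho[r] = eta / s3;
  }
  return List::create(_["lnphi"] = lnphi, _["Z"] = Z, _["rho"] = rho);
}
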