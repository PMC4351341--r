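#include <Rcpp.h>
using namespace Rcpp;

// Units: Angstrom, fs, amu, kcal/mol.

static inline void min_image(double* d, const double* cell, const int* pbc) {
  for (int k = 0; k < 3; ++k) {
    if (pbc[k] && cell[k] > 0.0) d[k] -= cell[k] * std::round(d[k] / cell[k]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_dist(NumericMatrix X, NumericMatrix Y,
                             NumericVector cell, LogicalVector pbc) {
  const int n = X.nrow(), m = Y.nrow();
  NumericMatrix D(n, m);
  double c[3];
  int p[3];
  for (int k = 0; k < 3; ++k) { c[k] = cell[k]; p[k] = pbc[k] ? 1 : 0; }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d[3] = {X(i, 0) - Y(j, 0), X(i, 1) - Y(j, 1), X(i, 2) - Y(j, 2)};
      min_image(d, c, p);
      D(i, j) = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    }
  }
  return D;
}

// Per species-pair parameters of one model, flattened with cutoff shifts
// precomputed so the hot loop is branch-light.
struct PairTable {
  int ns;
  std::vector<double> eps, rmin, rcut, uc, fc;      // LJ + shifts at rcut
  std::vector<double> geps, gr0, gw, grcut, guc, gfc; // Gaussian + shifts
  std::vector<double> rmax2; // squared outer cutoff (max of both terms)
};

// LJ in rmin form: u(r) = eps*(x^12 - 2 x^6), x = rmin/r; f = -du/dr.
static inline void lj_uf(double eps, double rmin, double r, double& u,
                         double& f) {
  double x = rmin / r;
  double x3 = x * x * x, x6 = x3 * x3, x12 = x6 * x6;
  u = eps * (x12 - 2.0 * x6);
  f = 12.0 * eps * (x12 - x6) / r;
}

static inline void gauss_uf(double geps, double gr0, double gw, double r,
                            double& u, double& f) {
  double z = (r - gr0) / gw;
  double e = std::exp(-0.5 * z * z);
  u = -geps * e;
  f = -geps * e * z / gw;
}

static PairTable buildTable(List p) {
  NumericMatrix eps = as<NumericMatrix>(p["eps"]);
  NumericMatrix rmin = as<NumericMatrix>(p["rmin"]);
  NumericMatrix rcut = as<NumericMatrix>(p["rcut"]);
  NumericMatrix geps = as<NumericMatrix>(p["geps"]);
  NumericMatrix gr0 = as<NumericMatrix>(p["gr0"]);
  NumericMatrix gw = as<NumericMatrix>(p["gw"]);
  NumericMatrix grcut = as<NumericMatrix>(p["grcut"]);
  PairTable t;
  t.ns = eps.nrow();
  int nn = t.ns * t.ns;
  t.eps.resize(nn); t.rmin.resize(nn); t.rcut.resize(nn);
  t.uc.resize(nn); t.fc.resize(nn);
  t.geps.resize(nn); t.gr0.resize(nn); t.gw.resize(nn); t.grcut.resize(nn);
  t.guc.resize(nn); t.gfc.resize(nn);
  t.rmax2.resize(nn);
  for (int i = 0; i < t.ns; ++i) {
    for (int j = 0; j < t.ns; ++j) {
      int k = i * t.ns + j;
      t.eps[k] = eps(i, j); t.rmin[k] = rmin(i, j); t.rcut[k] = rcut(i, j);
      t.geps[k] = geps(i, j); t.gr0[k] = gr0(i, j); t.gw[k] = gw(i, j);
      t.grcut[k] = grcut(i, j);
      double rmax = 0.0;
      if (t.eps[k] > 0.0) {
        lj_uf(t.eps[k], t.rmin[k], t.rcut[k], t.uc[k], t.fc[k]);
        rmax = std::max(rmax, t.rcut[k]);
      } else { t.uc[k] = t.fc[k] = 0.0; }
      if (t.geps[k] != 0.0) {
        gauss_uf(t.geps[k], t.gr0[k], t.gw[k], t.grcut[k], t.guc[k],
                 t.gfc[k]);
        rmax = std::max(rmax, t.grcut[k]);
      } else { t.guc[k] = t.gfc[k] = 0.0; }
      t.rmax2[k] = rmax * rmax;
    }
  }
  return t;
}

// shifted-force pair interaction from a prebuilt table
static inline void pair_uf(const PairTable& t, int k, double r, double& u,
                           double& f) {
  u = 0.0; f = 0.0;
  if (t.eps[k] > 0.0 && r < t.rcut[k]) {
    double u0, f0;
    lj_uf(t.eps[k], t.rmin[k], r, u0, f0);
    u += u0 - t.uc[k] + (r - t.rcut[k]) * t.fc[k];
    f += f0 - t.fc[k];
  }
  if (t.geps[k] != 0.0 && r < t.grcut[k]) {
    double u0, f0;
    gauss_uf(t.geps[k], t.gr0[k], t.gw[k], r, u0, f0);
    u += u0 - t.guc[k] + (r - t.grcut[k]) * t.gfc[k];
    f += f0 - t.gfc[k];
  }
}

// Composite two-model pair/bond/angle force evaluation.
// An intermolecular pair uses model A iff both atoms are flagged qmAtom;
// bonded (bond/angle) terms use model A iff the owning molecule is wholly
// inside the QM set (qmMolAtom flag, per atom).
// [[Rcpp::export]]
List cpp_pair_forces(NumericMatrix pos, NumericVector cell, LogicalVector pbc,
                     IntegerVector speciesIdx, IntegerVector molId,
                     LogicalVector qmAtom, LogicalVector qmMolAtom,
                     List parA, List parB,
                     IntegerMatrix bonds, NumericVector kbA, NumericVector b0A,
                     NumericVector kbB, NumericVector b0B,
                     IntegerMatrix angles, NumericVector kthA, NumericVector th0A,
                     NumericVector kthB, NumericVector th0B) {
  const int n = pos.nrow();
  PairTable A = buildTable(parA), B = buildTable(parB);
  const int ns = A.ns;
  NumericMatrix F(n, 3);
  double* Fp = REAL(F);
  double c[3];
  int p[3];
  bool periodic = false;
  for (int k = 0; k < 3; ++k) {
    c[k] = cell[k];
    p[k] = pbc[k] ? 1 : 0;
    if (p[k]) periodic = true;
  }
  double energy = 0.0;

  // flat copies for the hot loop
  std::vector<double> x(n), y(n), z(n);
  std::vector<int> sp(n), mol(n), qa(n), qm(n);
  const double* posp = REAL(pos);
  // wrap working coordinates into the primary cell so pair wrapping below
  // needs at most one +/- cell correction (dynamics keep unwrapped
  // coordinates; forces are translation invariant)
  for (int i = 0; i < n; ++i) {
    x[i] = posp[i]; y[i] = posp[i + n]; z[i] = posp[i + 2 * n];
    if (p[0]) x[i] -= c[0] * std::floor(x[i] / c[0]);
    if (p[1]) y[i] -= c[1] * std::floor(y[i] / c[1]);
    if (p[2]) z[i] -= c[2] * std::floor(z[i] / c[2]);
    sp[i] = speciesIdx[i] - 1;
    mol[i] = molId[i];
    qa[i] = qmAtom[i] ? 1 : 0;
    qm[i] = qmMolAtom[i] ? 1 : 0;
  }
  double rmax2all = 0.0;
  for (int k = 0; k < ns * ns; ++k) {
    rmax2all = std::max(rmax2all, std::max(A.rmax2[k], B.rmax2[k]));
  }

  const double h0 = 0.5 * c[0], h1 = 0.5 * c[1], h2 = 0.5 * c[2];

  // intermolecular nonbonded
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    const int moli = mol[i], qai = qa[i], spi = sp[i] * ns;
    for (int j = i + 1; j < n; ++j) {
      if (moli == mol[j]) continue;
      double d0 = xi - x[j], d1 = yi - y[j], d2 = zi - z[j];
      if (periodic) {
        if (p[0]) { if (d0 > h0) d0 -= c[0]; else if (d0 < -h0) d0 += c[0]; }
        if (p[1]) { if (d1 > h1) d1 -= c[1]; else if (d1 < -h1) d1 += c[1]; }
        if (p[2]) { if (d2 > h2) d2 -= c[2]; else if (d2 < -h2) d2 += c[2]; }
      }
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      if (r2 >= rmax2all) continue;
      const PairTable& T = (qai && qa[j]) ? A : B;
      int k = spi + sp[j];
      if (r2 >= T.rmax2[k]) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) stop("coincident atoms in nonbonded evaluation");
      double u, f;
      pair_uf(T, k, r, u, f);
      energy += u;
      double fr = f / r;
      Fp[i] += fr * d0; Fp[i + n] += fr * d1; Fp[i + 2 * n] += fr * d2;
      Fp[j] -= fr * d0; Fp[j + n] -= fr * d1; Fp[j + 2 * n] -= fr * d2;
    }
  }

  // bonds: u = 0.5 kb (r - b0)^2
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    bool useA = qm[i];
    double kb = useA ? kbA[b] : kbB[b];
    double b0 = useA ? b0A[b] : b0B[b];
    double d[3] = {x[i] - x[j], y[i] - y[j], z[i] - z[j]};
    min_image(d, c, p);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r < 1e-12) stop("coincident bonded atoms");
    double du = kb * (r - b0);
    energy += 0.5 * kb * (r - b0) * (r - b0);
    double fr = -du / r;
    for (int k = 0; k < 3; ++k) {
      Fp[i + k * n] += fr * d[k];
      Fp[j + k * n] -= fr * d[k];
    }
  }

  // angles: u = 0.5 kth (theta - th0)^2, apex is the middle index
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0) - 1, j = angles(a, 1) - 1, kk = angles(a, 2) - 1;
    bool useA = qm[j];
    double kth = useA ? kthA[a] : kthB[a];
    double th0 = useA ? th0A[a] : th0B[a];
    double rij[3] = {x[i] - x[j], y[i] - y[j], z[i] - z[j]};
    double rkj[3] = {x[kk] - x[j], y[kk] - y[j], z[kk] - z[j]};
    min_image(rij, c, p);
    min_image(rkj, c, p);
    double nij = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
    double cth = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij * nkj);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
    double dU = kth * (th - th0);
    energy += 0.5 * kth * (th - th0) * (th - th0);
    for (int k = 0; k < 3; ++k) {
      double dthi = (cth * rij[k] / nij - rkj[k] / nkj) / (nij * sth);
      double dthk = (cth * rkj[k] / nkj - rij[k] / nij) / (nkj * sth);
      Fp[i + k * n] -= dU * dthi;
      Fp[kk + k * n] -= dU * dthk;
      Fp[j + k * n] += dU * (dthi + dthk);
    }
  }

  return List::create(_["forces"] = F, _["energy"] = energy);
}
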