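#include <Rcpp.h>
using namespace Rcpp;

// Units: Angstrom, fs, amu, kcal/mol. Velocity in A/fs.
static const double KB = 1.987204259e-3;   // kcal/mol/K
static const double ACC = 4.184e-4;        // (kcal/mol/A)/amu -> A/fs^2

// kinetic energy of one DOF in kcal/mol ("p^2/m")
static inline double dof_ke(double m, double v) { return m * v * v / ACC; }

// exact Ornstein-Uhlenbeck update for dv = -c v dt + sqrt(2 g s2) dW where
// the stationary variance at c = g is s2; general c (may be <= 0):
// v <- e^{-c h} v + sqrt(g * S(c,h) * 2 s2 / 2) eta with
// S = (1 - e^{-2 c h}) / c (-> 2h as c -> 0).
static inline double ou_update(double v, double c, double h, double g,
                               double s2) {
  double decay = std::exp(-c * h);
  double S;
  if (std::fabs(c) * h < 1e-10) S = 2.0 * h;
  else S = -std::expm1(-2.0 * c * h) / c;
  double var = g * S * s2;
  double nv = decay * v;
  if (g > 0.0) nv += std::sqrt(std::max(0.0, var)) * norm_rand();
  return nv;
}

// Adaptive Langevin coupling phase over dt, per DOF (massive mode):
//   chi_half -> exact OU with total friction (chi + gamma) -> chi_half
// chi obeys dchi/dt = (p^2/m - kB T)/Q, Q = kB T tauNH^2 (n = 1).
// [[Rcpp::export]]
List cpp_adl_phase(NumericVector v, NumericVector chi, NumericVector m,
                   double dt, double gamma, double Q, double kBT,
                   bool freezeChi) {
  int nd = v.size();
  NumericVector vv = clone(v), cc = clone(chi);
  double h = 0.5 * dt;
  for (int i = 0; i < nd; ++i) {
    if (!freezeChi) cc[i] += h * (dof_ke(m[i], vv[i]) - kBT) / Q;
    double s2 = kBT * ACC / m[i]; // stationary velocity variance
    vv[i] = ou_update(vv[i], cc[i] + gamma, dt, gamma, s2);
    if (!freezeChi) cc[i] += h * (dof_ke(m[i], vv[i]) - kBT) / Q;
  }
  return List::create(_["v"] = vv, _["chi"] = cc);
}

// One half sweep of the Nose-Hoover chain with terminal Langevin
// thermalization, for a single DOF. xi points to r chain variables.
static inline void nhc_half(double* xi, int r, double& v, double m, double h,
                            double gammaL, double Q, double kBT) {
  for (int i = r - 1; i >= 0; --i) {
    if (i == r - 1 && gammaL > 0.0) {
      // exact OU: dxi_r = -gammaL xi_r dt + sqrt(2 gammaL kBT / Q) dW
      xi[i] = ou_update(xi[i], gammaL, 0.5 * h, gammaL, kBT / Q);
    }
    double G;
    if (i == 0) G = (dof_ke(m, v) - kBT) / Q;
    else G = (Q * xi[i - 1] * xi[i - 1] - kBT) / Q;
    if (i < r - 1) {
      double s = std::exp(-0.5 * h * xi[i + 1]);
      xi[i] = (xi[i] * s + h * G) * s;
    } else {
      xi[i] += h * G;
    }
    if (i == r - 1 && gammaL > 0.0) {
      xi[i] = ou_update(xi[i], gammaL, 0.5 * h, gammaL, kBT / Q);
    }
  }
  v *= std::exp(-h * xi[0]);
}

// Adaptive NHC-Langevin coupling phase over dt (two half sweeps per DOF).
// xi is nd x r; all chain masses Q_i = kB T tauNH^2.
// [[Rcpp::export]]
List cpp_nhcl_phase(NumericVector v, NumericMatrix xi, NumericVector m,
                    double dt, double gammaL, double Q, double kBT) {
  int nd = v.size(), r = xi.ncol();
  NumericVector vv = clone(v);
  NumericMatrix xx = clone(xi);
  std::vector<double> chain(r);
  for (int i = 0; i < nd; ++i) {
    for (int j = 0; j < r; ++j) chain[j] = xx(i, j);
    double vi = vv[i];
    nhc_half(chain.data(), r, vi, m[i], 0.5 * dt, gammaL, Q, kBT);
    nhc_half(chain.data(), r, vi, m[i], 0.5 * dt, gammaL, Q, kBT);
    vv[i] = vi;
    for (int j = 0; j < r; ++j) xx(i, j) = chain[j];
  }
  return List::create(_["v"] = vv, _["xi"] = xx);
}

// Long-run adaptive-Langevin sampler for independent harmonic oscillators,
// used for stationary-statistics checks. Optional constant stochastic
// "stirring" kick (sd per step, A/fs) models nonconservative heating; the
// freezeChi flag disables the Nose-Hoover compensation for comparison.
// [[Rcpp::export]]
List cpp_harmonic_adl_run(int nsteps, double dt, NumericVector m,
                          NumericVector omega, double gamma, double tauNH,
                          double temp, NumericVector q0, NumericVector v0,
                          double stirSd, bool freezeChi, int sampleEvery) {
  int nd = q0.size();
  std::vector<double> q(q0.begin(), q0.end()), v(v0.begin(), v0.end()),
      chi(nd, 0.0);
  double kBT = KB * temp, Q = kBT * tauNH * tauNH;
  NumericVector sumQ2(nd), sumV2(nd), sumChi(nd);
  std::vector<double> qs;
  double h = 0.5 * dt;
  for (int s = 0; s < nsteps; ++s) {
    if (stirSd > 0.0)
      for (int i = 0; i < nd; ++i) v[i] += stirSd * norm_rand();
    for (int i = 0; i < nd; ++i) {
      // palindromic B(h) [chi O chi](h) A(dt) [chi O chi](h) B(h) splitting
      v[i] += -omega[i] * omega[i] * q[i] * h; // B half
      if (!freezeChi) chi[i] += 0.5 * h * (dof_ke(m[i], v[i]) - kBT) / Q;
      v[i] = ou_update(v[i], chi[i] + gamma, h, gamma, kBT * ACC / m[i]);
      if (!freezeChi) chi[i] += 0.5 * h * (dof_ke(m[i], v[i]) - kBT) / Q;
      q[i] += v[i] * dt; // A
      if (!freezeChi) chi[i] += 0.5 * h * (dof_ke(m[i], v[i]) - kBT) / Q;
      v[i] = ou_update(v[i], chi[i] + gamma, h, gamma, kBT * ACC / m[i]);
      if (!freezeChi) chi[i] += 0.5 * h * (dof_ke(m[i], v[i]) - kBT) / Q;
      v[i] += -omega[i] * omega[i] * q[i] * h; // B half
      sumQ2[i] += q[i] * q[i];
      sumV2[i] += v[i] * v[i];
      sumChi[i] += chi[i];
    }
    if (sampleEvery > 0 && (s + 1) % sampleEvery == 0) qs.push_back(q[0]);
  }
  return List::create(_["meanQ2"] = sumQ2 / nsteps,
                      _["meanV2"] = sumV2 / nsteps,
                      _["meanChi"] = sumChi / nsteps,
                      _["qSamples"] = wrap(qs),
                      _["finalQ"] = wrap(q), _["finalV"] = wrap(v),
                      _["finalChi"] = wrap(chi));
}

// Long-run NHC-Langevin sampler for independent harmonic oscillators.
// Tracks the extended-system invariant when gammaL = 0 (conservative chain):
// H_ext = sum_dof [ke + pot + sum_i Q xi_i^2 / 2 + kBT eta_i] with
// deta_i/dt = xi_i accumulated by trapezoid.
// [[Rcpp::export]]
List cpp_harmonic_nhcl_run(int nsteps, double dt, NumericVector m,
                           NumericVector omega, int r, double gammaL,
                           double tauNH, double temp, NumericVector q0,
                           NumericVector v0, int sampleEvery) {
  int nd = q0.size();
  std::vector<double> q(q0.begin(), q0.end()), v(v0.begin(), v0.end());
  std::vector<double> xi(nd * r, 0.0), eta(nd * r, 0.0);
  double kBT = KB * temp, Q = kBT * tauNH * tauNH;
  NumericVector sumQ2(nd), sumV2(nd);
  std::vector<double> invariant;
  double h = 0.5 * dt;
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < nd; ++i) {
      std::vector<double> xi0(r);
      for (int j = 0; j < r; ++j) xi0[j] = xi[i * r + j];
      // palindromic splitting, as in the MD loop: half kick, chain half,
      // drift, chain half, half kick
      double vi = v[i];
      vi += -omega[i] * omega[i] * q[i] * h;
      nhc_half(&xi[i * r], r, vi, m[i], h, gammaL, Q, kBT);
      q[i] += vi * dt;
      nhc_half(&xi[i * r], r, vi, m[i], h, gammaL, Q, kBT);
      vi += -omega[i] * omega[i] * q[i] * h;
      v[i] = vi;
      for (int j = 0; j < r; ++j)
        eta[i * r + j] += 0.5 * dt * (xi0[j] + xi[i * r + j]);
      sumQ2[i] += q[i] * q[i];
      sumV2[i] += v[i] * v[i];
    }
    if (sampleEvery > 0 && (s + 1) % sampleEvery == 0) {
      double H = 0.0;
      for (int i = 0; i < nd; ++i) {
        H += dof_ke(m[i], v[i]) / 2.0 +
             0.5 * m[i] * omega[i] * omega[i] * q[i] * q[i] / ACC;
        for (int j = 0; j < r; ++j)
          H += 0.5 * Q * xi[i * r + j] * xi[i * r + j] + kBT * eta[i * r + j];
      }
      invariant.push_back(H);
    }
  }
  NumericMatrix xiOut(nd, r);
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < r; ++j) xiOut(i, j) = xi[i * r + j];
  return List::create(_["meanQ2"] = sumQ2 / nsteps,
                      _["meanV2"] = sumV2 / nsteps,
                      _["invariant"] = wrap(invariant),
                      _["finalQ"] = wrap(q), _["finalV"] = wrap(v),
                      _["finalXi"] = xiOut);
}
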