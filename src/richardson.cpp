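#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cplx;

// (1 - exp(-a h)) / a, stable for small a
static inline double om_exp(double a, double h) {
  if (std::abs(a * h) < 1e-12) return h;
  return -std::expm1(-a * h) / a;
}

// Threshold integration of the stationary Fokker-Planck problem
//   0 = -d/dv [ A(v) P - d/dv (D(v) P) ],   J = A P - (D P)'
// with absorbing boundary at v = theta (last node), reinjection of the
// threshold flux at the reset node ir (0-based), and an unnormalized
// threshold flux of 1.  Integrates q = D P downward:
//   dq/dv = (A/D) q - J,  J = 1 above the reset node, 0 below.
// Returns P (unnormalized), the probability mass I0 = int P dv and the
// refractory-corrected rate nu0 = 1 / (I0 + tau_ref).
// [[Rcpp::export]]
List ri_steady_cpp(NumericVector Dnode, NumericVector Amid,
                   NumericVector Dmid, double h, int ir, double tau_ref) {
  const int m = Dnode.size();
  NumericVector P(m), q(m);
  q[m - 1] = 0.0;
  P[m - 1] = 0.0;
  for (int k = m - 1; k >= 1; --k) {
    const double a = Amid[k - 1] / Dmid[k - 1];
    const double b = (k - 1 >= ir) ? -1.0 : 0.0; // dq/dv = a q + b
    q[k - 1] = q[k] * std::exp(-a * h) - b * om_exp(a, h);
    if (q[k - 1] > 1e280) q[k - 1] = 1e280; // deeply subthreshold guard
    P[k - 1] = q[k - 1] / Dnode[k - 1];
  }
  double I0 = 0.0;
  for (int k = 0; k < m - 1; ++k) I0 += 0.5 * (P[k] + P[k + 1]) * h;
  const double nu0 = 1.0 / (I0 + tau_ref);
  return List::create(_["P"] = P, _["q"] = q, _["I0"] = I0,
                      _["nu0"] = nu0);
}

// Linearization of the stationary sweep with respect to a parameter that
// perturbs drift and diffusion by (A1, D1): returns the first-order change
// dI of the (unnormalized) probability mass, from which the zero-frequency
// susceptibility is A(0) = -nu0^2 * dI.
// [[Rcpp::export]]
double ri_steady_delta_cpp(NumericVector Dnode, NumericVector Amid,
                           NumericVector Dmid, NumericVector A1mid,
                           NumericVector D1mid, NumericVector D1node,
                           NumericVector q, NumericVector P,
                           double h, int ir) {
  const int m = Dnode.size();
  std::vector<double> dP(m);
  double dq = 0.0;
  dP[m - 1] = 0.0;
  for (int k = m - 1; k >= 1; --k) {
    const double D = Dmid[k - 1];
    const double a = Amid[k - 1] / D;
    const double da = (A1mid[k - 1] * D - Amid[k - 1] * D1mid[k - 1])
                      / (D * D);
    const double q0m = 0.5 * (q[k] + q[k - 1]);
    const double g = da * q0m; // d(dq)/dv = a dq + g
    dq = dq * std::exp(-a * h) - g * om_exp(a, h);
    dP[k - 1] = dq / Dnode[k - 1]
                - q[k - 1] * D1node[k - 1] / (Dnode[k - 1] * Dnode[k - 1]);
  }
  double dI = 0.0;
  for (int k = 0; k < m - 1; ++k) dI += 0.5 * (dP[k] + dP[k + 1]) * h;
  return dI;
}

// One downward sweep of the frequency-domain boundary-value problem
//   i w P1 = -dJ1/dv (+ reinjection at the reset node)
//   J1 = A P1 + A1 P0 - d/dv (D P1 + D1 P0)
// With q1 = D P1 + D1 P0:  dq1/dv = a q1 + (A1 - a D1) P0 - J1.
// jtheta: threshold flux boundary value (1 for the homogeneous problem,
// 0 for an inhomogeneous one).  reinj: flux subtracted when crossing the
// reset node downward (exp(-i w tau_ref) * jtheta for the reinjection
// problem, 1 for the first-passage source problem, 0 otherwise).
// Returns J1 at the lower boundary.
static cplx sweep_spectral(double omega, const double* Dnode,
                           const double* Amid, const double* Dmid,
                           const double* A1mid, const double* D1mid,
                           const double* D1node, const double* P0node,
                           const double* P0mid, int m, double h, int ir,
                           cplx jtheta, cplx reinj) {
  const cplx I(0.0, 1.0);
  cplx q(0.0, 0.0), J = jtheta, p_up(0.0, 0.0);
  for (int k = m - 1; k >= 1; --k) {
    const double D = Dmid[k - 1];
    const double a = Amid[k - 1] / D;
    cplx b = -J;
    if (A1mid) b += (A1mid[k - 1] - a * D1mid[k - 1]) * P0mid[k - 1];
    q = q * std::exp(-a * h) - b * om_exp(a, h);
    cplx p = q / Dnode[k - 1];
    if (D1node) p -= D1node[k - 1] * P0node[k - 1] / Dnode[k - 1];
    J += I * omega * h * 0.5 * (p + p_up);
    if (k - 1 == ir) J -= reinj; // flux discontinuity at the reset node
    p_up = p;
  }
  return J;
}

// Frequency-domain threshold integration for one cell: for each angular
// frequency (rad/ms) computes the first-passage-time density transform
// f(w) (for the renewal spike-train spectrum) and the susceptibility of
// the firing rate to each parameter whose drift/diffusion perturbations
// (A1, D1) are supplied as columns.
// P0node/P0mid: normalized stationary density (mass + nu0*tau_ref = 1).
// Returns a complex matrix, one row per frequency; first column f, then
// one column per parameter.
// [[Rcpp::export]]
ComplexMatrix ri_spectral_batch_cpp(NumericVector omegas,
                                    NumericVector Dnode, NumericVector Amid,
                                    NumericVector Dmid,
                                    NumericMatrix A1mids,
                                    NumericMatrix D1mids,
                                    NumericMatrix D1nodes,
                                    NumericVector P0node,
                                    NumericVector P0mid,
                                    double h, int ir, double tau_ref,
                                    double nu0) {
  const int m = Dnode.size();
  const int nw = omegas.size();
  const int np = A1mids.ncol();
  ComplexMatrix out(nw, np + 1);
  for (int w = 0; w < nw; ++w) {
    const double omega = omegas[w];
    const cplx phase = std::exp(cplx(0.0, -omega * tau_ref));
    // first-passage transform: no reinjection homogeneous + unit source
    cplx jA = sweep_spectral(omega, &Dnode[0], &Amid[0], &Dmid[0],
                             nullptr, nullptr, nullptr, nullptr, nullptr,
                             m, h, ir, cplx(1, 0), cplx(0, 0));
    cplx jB = sweep_spectral(omega, &Dnode[0], &Amid[0], &Dmid[0],
                             nullptr, nullptr, nullptr, nullptr, nullptr,
                             m, h, ir, cplx(0, 0), cplx(1, 0));
    cplx f = -jB / jA;
    out(w, 0) = Rcomplex{f.real(), f.imag()};
    // susceptibilities: homogeneous problem with delayed reinjection
    cplx jh = sweep_spectral(omega, &Dnode[0], &Amid[0], &Dmid[0],
                             nullptr, nullptr, nullptr, nullptr, nullptr,
                             m, h, ir, cplx(1, 0), phase);
    for (int p = 0; p < np; ++p) {
      cplx ji = sweep_spectral(omega, &Dnode[0], &Amid[0], &Dmid[0],
                               &A1mids(0, p), &D1mids(0, p), &D1nodes(0, p),
                               &P0node[0], &P0mid[0],
                               m, h, ir, cplx(0, 0), cplx(0, 0));
      cplx A = -ji / jh;
      out(w, p + 1) = Rcomplex{A.real(), A.imag()};
    }
    if ((w & 0x0F) == 0) Rcpp::checkUserInterrupt();
  }
  (void)nu0;
  return out;
}

// First and second moments of the first-passage time from the reset node
// to threshold, via the backward equations D T'' + A T' = -1 (and -2 T1),
// reflecting at the lower bound, absorbing at threshold.
// [[Rcpp::export]]
List ri_fpt_moments_cpp(NumericVector Dnode, NumericVector Amid,
                        NumericVector Dmid, double h, int ir) {
  const int m = Dnode.size();
  std::vector<double> u(m), T1(m);
  u[0] = 0.0;
  for (int k = 0; k < m - 1; ++k) {
    const double a = Amid[k] / Dmid[k];
    const double beta = -1.0 / Dmid[k]; // du/dv = -a u + beta
    u[k + 1] = u[k] * std::exp(-a * h) + beta * om_exp(a, h);
  }
  T1[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k)
    T1[k] = T1[k + 1] - 0.5 * (u[k] + u[k + 1]) * h;
  std::vector<double> w(m), T2(m);
  w[0] = 0.0;
  for (int k = 0; k < m - 1; ++k) {
    const double a = Amid[k] / Dmid[k];
    const double beta = -2.0 * 0.5 * (T1[k] + T1[k + 1]) / Dmid[k];
    w[k + 1] = w[k] * std::exp(-a * h) + beta * om_exp(a, h);
  }
  T2[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k)
    T2[k] = T2[k + 1] - 0.5 * (w[k] + w[k + 1]) * h;
  return List::create(_["T1"] = T1[ir], _["T2"] = T2[ir]);
}
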