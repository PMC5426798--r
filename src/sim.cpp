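#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Euler-Maruyama integration of the conductance-based LIF network.
//
// Voltage (sub-threshold):
//   tau_m dv = [-v - gE (v - E_E) - gI (v - E_I)] dt + sigma sqrt(tau_m) dW
// Synapses (second-order alpha kinetics, source-type constants):
//   tau_d dg  = (g1 - g) dt
//   tau_r dg1 = -g1 dt   (+ jump of amp on each presynaptic spike)
// Spike: v >= theta  ->  count spike, deliver jumps, hold v for tau_ref,
// then release from the reset potential 0.
//
// Connectivity is passed in CSR-by-source form (0-based): targets of source
// j are tgt[src_ptr[j] .. src_ptr[j+1]-1] with per-edge amplitudes amp.
// [[Rcpp::export]]
List sim_network_cpp(IntegerVector cell_type, NumericVector theta,
                     NumericVector sigma, double tau_m, double tau_ref,
                     NumericVector tau_r, NumericVector tau_d,
                     double E_E, double E_I,
                     IntegerVector src_ptr, IntegerVector tgt,
                     NumericVector amp,
                     double dt, int steps_per_real, int equil_steps,
                     int n_real, int bin_steps, double seed) {
  const int n = cell_type.size();
  if ((int)theta.size() != n || (int)sigma.size() != n)
    stop("parameter vectors must have one entry per cell");
  if (steps_per_real % bin_steps != 0)
    stop("bin width must divide the realization duration");
  const int nbins = steps_per_real / bin_steps;
  const int ref_steps = (int)std::ceil(tau_ref / dt - 1e-9);

  IntegerMatrix counts(n, nbins * (R_xlen_t)n_real);
  std::vector<double> v(n), gE(n), gI(n), g1E(n), g1I(n);
  std::vector<int> refr(n);
  std::vector<double> noise_coef(n), dt_tm(1);
  const double dtm = dt / tau_m;
  for (int i = 0; i < n; ++i) noise_coef[i] = sigma[i] * std::sqrt(dtm);
  const double decE = dt / tau_r[0], decI = dt / tau_r[1];
  const double dE = dt / tau_d[0], dI = dt / tau_d[1];

  Xoshiro256 rng((uint64_t)seed);
  std::vector<double> spikes_tot(n, 0.0);

  for (int r = 0; r < n_real; ++r) {
    // fresh initial conditions per realization, then equilibrate
    for (int i = 0; i < n; ++i) {
      v[i] = 0.0; gE[i] = gI[i] = g1E[i] = g1I[i] = 0.0; refr[i] = 0;
    }
    const int total = equil_steps + steps_per_real;
    for (int s = 0; s < total; ++s) {
      const bool recording = s >= equil_steps;
      const int bin = recording ? (s - equil_steps) / bin_steps : 0;
      const R_xlen_t col = (R_xlen_t)r * nbins + bin;
      for (int i = 0; i < n; ++i) {
        if (refr[i] > 0) {
          if (--refr[i] == 0) v[i] = 0.0;
        } else {
          const double vi = v[i];
          v[i] = vi + dtm * (-vi - gE[i] * (vi - E_E) - gI[i] * (vi - E_I))
                 + noise_coef[i] * rng.norm();
        }
        // conductance kinetics evolve during refractoriness too
        gE[i] += dE * (g1E[i] - gE[i]);
        gI[i] += dI * (g1I[i] - gI[i]);
        g1E[i] -= decE * g1E[i];
        g1I[i] -= decI * g1I[i];
      }
      for (int i = 0; i < n; ++i) {
        if (refr[i] == 0 && v[i] >= theta[i]) {
          if (recording) { counts(i, col)++; spikes_tot[i] += 1.0; }
          refr[i] = ref_steps;
          v[i] = 0.0;
          const int a = src_ptr[i], b = src_ptr[i + 1];
          if (cell_type[i] == 0)
            for (int e = a; e < b; ++e) g1E[tgt[e]] += amp[e];
          else
            for (int e = a; e < b; ++e) g1I[tgt[e]] += amp[e];
        }
      }
      if ((s & 0x3FFF) == 0) {
        if (!std::isfinite(v[0]) || !std::isfinite(gE[0]))
          stop("voltage diverged (NaN/Inf) at step %d of realization %d",
               s, r + 1);
        Rcpp::checkUserInterrupt();
      }
    }
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(v[i]))
        stop("voltage diverged (NaN/Inf) in realization %d", r + 1);
  }
  return List::create(_["counts"] = counts,
                      _["spikes_total"] = NumericVector(spikes_tot.begin(),
                                                        spikes_tot.end()));
}

// Single LIF cell driven by independent Poisson excitatory and inhibitory
// spike trains through the same second-order alpha synapses.  Used as a
// Monte-Carlo oracle for the diffusion mapping and the threshold-integration
// solver.  Rates are per ms.
// [[Rcpp::export]]
List sim_poisson_cell_cpp(double theta, double sigma, double tau_m,
                          double tau_ref,
                          NumericVector tau_r, NumericVector tau_d,
                          double E_E, double E_I,
                          double ahatE, double ahatI,
                          double rateE, double rateI,
                          double dt, int n_steps, int equil_steps,
                          int bin_steps, double seed) {
  const int ref_steps = (int)std::ceil(tau_ref / dt - 1e-9);
  const int nbins = n_steps / bin_steps;
  IntegerVector counts(nbins);
  double v = 0, gE = 0, gI = 0, g1E = 0, g1I = 0;
  int refr = 0;
  const double dtm = dt / tau_m;
  const double ncoef = sigma * std::sqrt(dtm);
  const double pE = rateE * dt, pI = rateI * dt;
  const double decE = dt / tau_r[0], decI = dt / tau_r[1];
  const double dE = dt / tau_d[0], dI = dt / tau_d[1];
  Xoshiro256 rng((uint64_t)seed);

  // accumulate conductance moments after equilibration
  double sE = 0, sE2 = 0, sI = 0, sI2 = 0;
  long nacc = 0;
  double nspk = 0;

  const int total = equil_steps + n_steps;
  for (int s = 0; s < total; ++s) {
    if (refr > 0) {
      if (--refr == 0) v = 0.0;
    } else {
      v += dtm * (-v - gE * (v - E_E) - gI * (v - E_I)) + ncoef * rng.norm();
    }
    gE += dE * (g1E - gE);
    gI += dI * (g1I - gI);
    g1E -= decE * g1E;
    g1I -= decI * g1I;
    if (pE > 0 && rng.u01() < pE) g1E += ahatE;
    if (pI > 0 && rng.u01() < pI) g1I += ahatI;
    if (s >= equil_steps) {
      sE += gE; sE2 += gE * gE; sI += gI; sI2 += gI * gI; ++nacc;
      if (refr == 0 && v >= theta) {
        counts[(s - equil_steps) / bin_steps]++;
        nspk += 1.0;
        refr = ref_steps;
        v = 0.0;
      }
    } else if (refr == 0 && v >= theta) {
      refr = ref_steps;
      v = 0.0;
    }
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  const double mE = sE / nacc, mI = sI / nacc;
  return List::create(_["counts"] = counts, _["n_spikes"] = nspk,
                      _["gE_mean"] = mE, _["gI_mean"] = mI,
                      _["gE_var"] = sE2 / nacc - mE * mE,
                      _["gI_var"] = sI2 / nacc - mI * mI);
}
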