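#' Single-cell operating point
#'
#' Bundles the six parameters that determine a cell's stationary statistics
#' once the network is reduced to an effective diffusion: mean excitatory
#' and inhibitory conductances, the standard deviations of their
#' fluctuations, the background-noise magnitude and the spiking threshold.
#' This is the argument list of the firing-rate function
#' `nu = f(<gI>, sigma_I, <gE>, sigma_E, sigma, theta)` on which the whole
#' susceptibility analysis rests.
#'
#' @param gE_mean,gI_mean mean synaptic conductances (dimensionless).
#' @param sigmaE,sigmaI SDs of the conductance fluctuations.
#' @param sigma background white-noise magnitude (scaled voltage).
#' @param theta spiking threshold (rest = 0).
#' @param tau_m,tau_ref membrane and refractory time constants (ms).
#' @param E_E,E_I synaptic reversal potentials.
#' @return A list of class `ei_point`.
#' @export
operating_point <- function(gE_mean = 0, gI_mean = 0, sigmaE = 0,
                            sigmaI = 0, sigma = 1, theta = 1,
                            tau_m = 20, tau_ref = 2,
                            E_E = 6.5, E_I = -0.5) {
  stopifnot(gE_mean >= 0, gI_mean >= 0, sigmaE >= 0, sigmaI >= 0,
            sigma > 0, theta > 0, tau_m > 0, tau_ref >= 0)
  g0 <- 1 + gE_mean + gI_mean
  mu <- (gE_mean * E_E + gI_mean * E_I) / g0
  sigma_eff2 <- (sigmaE^2 * (mu - E_E)^2 + sigmaI^2 * (mu - E_I)^2 +
                   sigma^2 * tau_m) / (g0 * tau_m)
  structure(list(gE_mean = gE_mean, gI_mean = gI_mean,
                 sigmaE = sigmaE, sigmaI = sigmaI, sigma = sigma,
                 theta = theta, tau_m = tau_m, tau_ref = tau_ref,
                 E_E = E_E, E_I = E_I,
                 g0 = g0, mu = mu, tau_eff = tau_m / g0,
                 sigma_eff2 = sigma_eff2),
            class = "ei_point")
}

# Voltage grid for the Fokker-Planck boundary-value problems: reset (0) is
# exactly on a node, theta is the top node, and the lower bound extends to
# min(-1, mu - 8 * stationary SD) so no stationary mass is truncated.
fp_grid <- function(pt, n_v = 2048) {
  sd_stat <- sqrt(max(pt$sigma_eff2, 1e-10) / 2)
  vmin_target <- min(-1, pt$mu - 8 * sd_stat)
  n_above <- max(round((n_v - 1) * pt$theta / (pt$theta - vmin_target)), 8)
  h <- pt$theta / n_above
  n_below <- max(ceiling(-vmin_target / h - 1e-9), 1)
  v <- (-n_below:n_above) * h
  list(v = v, h = h, ir = n_below) # ir is the 0-based reset node index
}

fp_drift <- function(pt, v) {
  (-v - pt$gE_mean * (v - pt$E_E) - pt$gI_mean * (v - pt$E_I)) / pt$tau_m
}

fp_diffusion <- function(pt, v) {
  (pt$sigmaE^2 * (v - pt$E_E)^2 + pt$sigmaI^2 * (v - pt$E_I)^2 +
     pt$sigma^2 * pt$tau_m) / (2 * pt$tau_m^2)
}

# drift/diffusion perturbations per unit change of each parameter
fp_perturbation <- function(pt, v, which) {
  zero <- numeric(length(v))
  switch(which,
    gE_mean = list(A1 = -(v - pt$E_E) / pt$tau_m, D1 = zero),
    gI_mean = list(A1 = -(v - pt$E_I) / pt$tau_m, D1 = zero),
    sigmaE2 = list(A1 = zero, D1 = (v - pt$E_E)^2 / (2 * pt$tau_m^2)),
    sigmaI2 = list(A1 = zero, D1 = (v - pt$E_I)^2 / (2 * pt$tau_m^2)),
    mu      = list(A1 = rep(pt$g0 / pt$tau_m, length(v)), D1 = zero),
    stop("unknown perturbation: ", which)
  )
}

fp_params <- c("gE_mean", "gI_mean", "sigmaE2", "sigmaI2", "mu")

# Stationary threshold-integration solve; rate in 1/ms.
fp_steady <- function(pt, n_v = 2048) {
  g <- fp_grid(pt, n_v)
  vm <- (g$v[-1] + g$v[-length(g$v)]) / 2
  Dnode <- fp_diffusion(pt, g$v)
  sol <- ri_steady_cpp(Dnode, fp_drift(pt, vm), fp_diffusion(pt, vm),
                       g$h, g$ir, pt$tau_ref)
  list(grid = g, Dnode = Dnode, Amid = fp_drift(pt, vm),
       Dmid = fp_diffusion(pt, vm),
       P = sol$P, q = sol$q, I0 = sol$I0, nu = sol$nu0)
}

# Zero-frequency susceptibility dnu/dparam (nu in 1/ms) via the analytic
# linearization of the stationary sweep.
fp_susc0 <- function(pt, which, steady = NULL, n_v = 2048) {
  s <- if (is.null(steady)) fp_steady(pt, n_v) else steady
  pn <- fp_perturbation(pt, s$grid$v, which)
  vm <- (s$grid$v[-1] + s$grid$v[-length(s$grid$v)]) / 2
  pm <- fp_perturbation(pt, vm, which)
  dI <- ri_steady_delta_cpp(s$Dnode, s$Amid, s$Dmid, pm$A1, pm$D1,
                            pn$D1, s$q, s$P, s$grid$h, s$grid$ir)
  -s$nu^2 * dI
}

#' Stationary firing rate by threshold integration
#'
#' Solves the stationary Fokker-Planck problem for the conductance-based
#' LIF with multiplicative (voltage-dependent) diffusion, absorbing
#' boundary at `theta`, reinjection at the reset potential 0 and a
#' refractory correction `1/(1/nu0 + tau_ref)`.
#'
#' @param point an [operating_point()].
#' @param n_v number of voltage grid points (default 2048).
#' @param check_grid if `TRUE`, re-solve with a doubled grid and warn when
#'   the rate moves by more than 1%.
#' @return Firing rate in Hz.
#' @examples
#' steady_rate(operating_point(sigma = 2 / sqrt(2), theta = 1))
#' @export
steady_rate <- function(point, n_v = 2048, check_grid = FALSE) {
  stopifnot(inherits(point, "ei_point"))
  nu <- fp_steady(point, n_v)$nu
  if (check_grid) {
    nu2 <- fp_steady(point, 2L * n_v)$nu
    if (abs(nu2 - nu) > 0.01 * max(nu, 1e-12))
      warning("rate changes by >1% on grid refinement; increase n_v")
  }
  1000 * nu
}

#' Default frequency grid for spectral quantities
#'
#' Zero plus a logarithmic grid from `f_min` to `f_max` Hz.  Zero frequency
#' is solved by its own stationary-derivative problem, so no numerical
#' omega -> 0 cancellation occurs.
#'
#' @param f_min,f_max grid limits in Hz.
#' @param n number of logarithmic points.
#' @return Numeric vector of frequencies in Hz (first entry 0).
#' @export
lr_frequency_grid <- function(f_min = 0.1, f_max = 1000, n = 61) {
  c(0, 10^seq(log10(f_min), log10(f_max), length.out = n))
}

#' Baseline spectrum and susceptibilities of one cell
#'
#' For a cell at a given operating point, computes the stationary rate, the
#' unperturbed spike-train power spectrum and the complex susceptibility of
#' the firing rate to modulation of each of `<gE>`, `<gI>`, `sigma_E^2`,
#' `sigma_I^2` and the effective potential `mu`, on a frequency grid.
#'
#' The spike train of an LIF with white noise is a renewal process, so the
#' baseline spectrum is assembled from the first-passage-time density
#' transform `f(omega)` (computed by threshold integration) as
#' `C0 = nu (1 - |F|^2)/|1 - F|^2` with `F = exp(-i omega tau_ref) f`; its
#' zero-frequency value `nu * CV^2` uses the first two first-passage
#' moments from the backward equations.  Susceptibilities at omega = 0 are
#' the exact parameter-derivatives of the stationary solve.
#'
#' @param point an [operating_point()].
#' @param freq frequency grid in Hz; see [lr_frequency_grid()].
#' @param n_v voltage grid points.
#' @return An object of class `ei_spectra`: list with `nu` (rate, 1/ms),
#'   `rate_hz`, `freq`, `C0` (power spectrum, 1/ms), `A` (complex matrix,
#'   one column per parameter), `A0` (named real vector of zero-frequency
#'   susceptibilities), `isi` (mean/var of the interspike interval), and
#'   the operating `point`.
#' @export
cell_spectra <- function(point, freq = lr_frequency_grid(), n_v = 2048) {
  stopifnot(inherits(point, "ei_point"))
  s <- fp_steady(point, n_v)
  g <- s$grid
  vm <- (g$v[-1] + g$v[-length(g$v)]) / 2
  # normalized stationary density: mass + nu * tau_ref = 1
  P0 <- s$P * s$nu
  P0mid <- (P0[-1] + P0[-length(P0)]) / 2
  A1m <- sapply(fp_params, function(p) fp_perturbation(point, vm, p)$A1)
  D1m <- sapply(fp_params, function(p) fp_perturbation(point, vm, p)$D1)
  D1n <- sapply(fp_params, function(p) fp_perturbation(point, g$v, p)$D1)
  pos <- freq > 0
  omega <- 2 * pi * freq[pos] / 1000 # rad/ms
  spec <- ri_spectral_batch_cpp(omega, s$Dnode, s$Amid, s$Dmid,
                                A1m, D1m, D1n, P0, P0mid,
                                g$h, g$ir, point$tau_ref, s$nu)
  f_fpt <- spec[, 1]
  Ftil <- exp(-1i * omega * point$tau_ref) * f_fpt
  C0pos <- s$nu * (1 - Mod(Ftil)^2) / Mod(1 - Ftil)^2
  mom <- ri_fpt_moments_cpp(s$Dnode, s$Amid, s$Dmid, g$h, g$ir)
  isi_mean <- mom$T1 + point$tau_ref
  isi_var <- mom$T2 - mom$T1^2
  A0 <- vapply(fp_params, function(p) fp_susc0(point, p, steady = s),
               numeric(1))
  nf <- length(freq)
  A <- matrix(0i, nf, length(fp_params),
              dimnames = list(NULL, fp_params))
  A[pos, ] <- spec[, -1, drop = FALSE]
  A[!pos, ] <- matrix(A0, sum(!pos), length(fp_params), byrow = TRUE)
  C0 <- numeric(nf)
  C0[pos] <- C0pos
  C0[!pos] <- s$nu * isi_var / isi_mean^2
  structure(list(nu = s$nu, rate_hz = 1000 * s$nu, freq = freq,
                 C0 = C0, A = A, A0 = A0,
                 isi = c(mean = isi_mean, var = isi_var),
                 point = point),
            class = "ei_spectra")
}

#' @export
print.ei_spectra <- function(x, ...) {
  cat(sprintf(
    "<ei_spectra> rate %.2f Hz, CV %.2f, %d frequencies (%.3g-%.4g Hz)\n",
    x$rate_hz, sqrt(x$isi["var"]) / x$isi["mean"], length(x$freq),
    min(x$freq), max(x$freq)))
  cat("  A(0):", paste(sprintf("%s=%.3g", names(x$A0), x$A0),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Susceptibility of the firing rate to one parameter
#'
#' @param point an [operating_point()].
#' @param which one of `"gE_mean"`, `"gI_mean"`, `"sigmaE2"`, `"sigmaI2"`,
#'   `"mu"`.
#' @param freq frequencies in Hz (0 allowed).
#' @param n_v voltage grid points.
#' @return Complex vector of rate responses (rate in 1/ms) per unit
#'   parameter modulation at each frequency.
#' @export
susceptibility <- function(point, which = "gI_mean", freq = 0,
                           n_v = 2048) {
  which <- match.arg(which, fp_params)
  sp <- cell_spectra(point, freq = unique(c(0, freq)), n_v = n_v)
  sp$A[match(freq, sp$freq), which]
}

#' Unperturbed spike-train power spectrum
#'
#' @inheritParams cell_spectra
#' @return Tibble with `freq` (Hz) and `power` (spectrum, 1/ms).
#' @export
unperturbed_power_spectrum <- function(point, freq = lr_frequency_grid(),
                                       n_v = 2048) {
  sp <- cell_spectra(point, freq = freq, n_v = n_v)
  tibble::tibble(freq = sp$freq, power = sp$C0)
}
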