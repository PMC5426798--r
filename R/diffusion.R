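#' Mean and variance of a Poisson-driven alpha conductance
#'
#' For a second-order alpha synapse (rise `tau_r`, decay `tau_d`, jump
#' amplitude `amplitude`) driven by Poisson spikes at `input_rate` Hz, the
#' stationary conductance has mean `amplitude * nu * tau_r` and variance
#' `amplitude^2 * nu * tau_r^2 / (2 (tau_r + tau_d))` with `nu` in 1/ms.
#'
#' @param input_rate total incoming spike rate (Hz); vectorized.
#' @param amplitude per-spike jump of the auxiliary conductance.
#' @param tau_r,tau_d rise and decay time constants (ms).
#' @return Tibble with columns `mean` and `variance`.
#' @examples
#' conductance_moments(100, 0.1, 1, 5)
#' @export
conductance_moments <- function(input_rate, amplitude, tau_r, tau_d) {
  stopifnot(all(input_rate >= 0), tau_r > 0, tau_d > 0)
  nu <- input_rate / 1000 # 1/ms
  tibble::tibble(
    mean = amplitude * nu * tau_r,
    variance = 0.5 * amplitude^2 * nu * tau_r * tau_r / (tau_r + tau_d)
  )
}

#' Effective current-based diffusion parameters
#'
#' Maps a conductance-based cell to its effective current-based diffusion:
#' total conductance `g0 = 1 + <gE> + <gI>`, effective potential
#' `mu = (<gE> E_E + <gI> E_I) / g0`, effective time constant
#' `tau_eff = tau_m / g0` and effective noise
#' `sigma_eff^2 = [sigmaE^2 (mu-E_E)^2 + sigmaI^2 (mu-E_I)^2 +
#' sigma^2 tau_m] / (g0 tau_m)`.
#'
#' @param gE_mean,gI_mean mean conductances (vectorized).
#' @param sigmaE,sigmaI conductance-fluctuation SDs.
#' @param sigma background-noise magnitude.
#' @param tau_m membrane time constant (ms).
#' @param E_E,E_I reversal potentials.
#' @return Tibble with columns `g0`, `mu`, `tau_eff`, `sigma_eff`.
#' @examples
#' effective_params(1, 1, 0, 0, sigma = 1)
#' @export
effective_params <- function(gE_mean, gI_mean, sigmaE = 0, sigmaI = 0,
                             sigma = 1, tau_m = 20,
                             E_E = 6.5, E_I = -0.5) {
  g0 <- 1 + gE_mean + gI_mean
  mu <- (gE_mean * E_E + gI_mean * E_I) / g0
  sigma_eff2 <- (sigmaE^2 * (mu - E_E)^2 + sigmaI^2 * (mu - E_I)^2 +
                   sigma^2 * tau_m) / (g0 * tau_m)
  tibble::tibble(g0 = g0, mu = mu, tau_eff = tau_m / g0,
                 sigma_eff = sqrt(sigma_eff2))
}

# Per-cell type-resolved input rates (1/ms) given the per-cell rate vector
# nu (1/ms): the sum over actual presynaptic partners, per Eq-free
# bookkeeping "sum_j W_ij nu_j" resolved by source type.
network_input_rates <- function(network, nu) {
  type <- network$cells$type
  adjE <- network$adjacency[, type == "E", drop = FALSE]
  adjI <- network$adjacency[, type == "I", drop = FALSE]
  list(E = as.numeric(adjE %*% nu[type == "E"]),
       I = as.numeric(adjI %*% nu[type == "I"]))
}

#' Per-cell operating points at given rates
#'
#' Accumulates each cell's type-resolved presynaptic rate over the actual
#' adjacency, converts rates to conductance moments, and returns one
#' operating point per cell.
#'
#' @param network an [ei_network()].
#' @param rates_hz per-cell firing rates in Hz.
#' @return Tibble with one row per cell: id, type, theta, input rates and
#'   the six operating-point parameters, plus the effective-diffusion
#'   parameters.
#' @export
cell_operating_points <- function(network, rates_hz) {
  stopifnot(length(rates_hz) == nrow(network$cells))
  syn <- network$config$syn
  cells <- network$cells
  nu <- rates_hz / 1000
  inp <- network_input_rates(network, nu)
  ampE <- network$amp[cells$type, "E"]
  ampI <- network$amp[cells$type, "I"]
  gE <- ampE * inp$E * syn$tau_r["E"]
  gI <- ampI * inp$I * syn$tau_r["I"]
  vE <- 0.5 * ampE^2 * inp$E * syn$tau_r["E"]^2 /
    (syn$tau_r["E"] + syn$tau_d["E"])
  vI <- 0.5 * ampI^2 * inp$I * syn$tau_r["I"]^2 /
    (syn$tau_r["I"] + syn$tau_d["I"])
  eff <- effective_params(gE, gI, sqrt(vE), sqrt(vI), cells$sigma,
                          tau_m = syn$tau_m,
                          E_E = syn$reversal["E"], E_I = syn$reversal["I"])
  dplyr::bind_cols(
    cells[, c("id", "type", "theta", "sigma")],
    tibble::tibble(rate_in_E = 1000 * inp$E, rate_in_I = 1000 * inp$I,
                   gE_mean = gE, gI_mean = gI,
                   sigmaE = sqrt(vE), sigmaI = sqrt(vI)),
    eff
  )
}

cell_point_from_row <- function(row, syn) {
  operating_point(gE_mean = row$gE_mean, gI_mean = row$gI_mean,
                  sigmaE = row$sigmaE, sigmaI = row$sigmaI,
                  sigma = row$sigma, theta = row$theta,
                  tau_m = syn$tau_m, tau_ref = syn$tau_ref,
                  E_E = unname(syn$reversal["E"]),
                  E_I = unname(syn$reversal["I"]))
}

# rate map nu -> f(nu) (1/ms in, 1/ms out)
rate_map <- function(network, nu, n_v = 2048) {
  ops <- cell_operating_points(network, 1000 * nu)
  syn <- network$config$syn
  vapply(seq_len(nrow(ops)), function(i) {
    fp_steady(cell_point_from_row(ops[i, ], syn), n_v)$nu
  }, numeric(1))
}

#' Self-consistent network firing rates
#'
#' Solves the network rate fixed point `nu_i = f_i(nu)` where `f_i` is the
#' threshold-integration rate of cell i at the operating point implied by
#' the rates of its actual presynaptic partners.  Damped Picard iteration
#' `nu <- (1 - damping) nu + damping f(nu)` seeded from the uncoupled
#' rates.
#'
#' @param network an [ei_network()].
#' @param init optional initial rate vector (Hz); default = uncoupled.
#' @param damping Picard damping factor in (0, 1].
#' @param tol relative fixed-point tolerance.
#' @param max_iter maximum iterations; non-convergence is an error whose
#'   condition carries the residual trajectory.
#' @param n_v voltage grid points for the solver.
#' @return Tibble (class `ei_rates`): id, type, theta, `rate_hz`; with
#'   attributes `residual` (final relative residual), `iterations` and
#'   `nu` (rates in 1/ms).
#' @export
self_consistent_rates <- function(network, init = NULL, damping = 0.5,
                                  tol = 1e-6, max_iter = 500,
                                  n_v = 2048) {
  stopifnot(inherits(network, "ei_network"))
  nu <- if (is.null(init)) rate_map(network, numeric(nrow(network$cells)),
                                    n_v)
        else init / 1000
  trail <- numeric(0)
  for (it in seq_len(max_iter)) {
    f <- rate_map(network, nu, n_v)
    res <- max(abs(f - nu)) / max(max(nu), 1e-12)
    trail <- c(trail, res)
    nu <- (1 - damping) * nu + damping * f
    if (res < tol) break
  }
  if (res >= tol) {
    cond <- simpleError(sprintf(
      "self-consistent rates did not converge in %d iterations (residual %.3g)",
      max_iter, res))
    cond$residuals <- trail
    stop(cond)
  }
  out <- dplyr::bind_cols(network$cells[, c("id", "type", "theta")],
                          tibble::tibble(rate_hz = 1000 * nu))
  attr(out, "residual") <- res
  attr(out, "iterations") <- it
  attr(out, "nu") <- nu
  class(out) <- c("ei_rates", class(out))
  out
}
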