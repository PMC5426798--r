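#' Fourier transform of the unit-area synaptic kernel
#'
#' The second-order alpha synapse has a unit-area double-exponential
#' kernel whose transform (convention `exp(-2 pi i f t)`, `f` in Hz,
#' times in ms) is `1 / ((1 + i w tau_r)(1 + i w tau_d))` with
#' `w = 2 pi f / 1000` rad/ms.
#'
#' @param tau_r,tau_d rise and decay constants (ms).
#' @param freq frequencies in Hz (vectorized).
#' @return Complex vector; equals 1 at `freq = 0`.
#' @export
synaptic_filter_ft <- function(tau_r, tau_d, freq) {
  stopifnot(tau_r > 0, tau_d > 0)
  w <- 2 * pi * freq / 1000
  1 / ((1 + 1i * w * tau_r) * (1 + 1i * w * tau_d))
}

#' Linear-response operating point of a network
#'
#' Runs the full single-cell stage of the linear-response calculation:
#' self-consistent rates, then per-cell baseline spectra and the four
#' conductance susceptibilities (plus the current susceptibility) on a
#' frequency grid.
#'
#' @param network an [ei_network()].
#' @param rates optional precomputed [self_consistent_rates()] result.
#' @param freq frequency grid in Hz (must include 0).
#' @param n_v voltage grid points for the solver.
#' @return Object of class `ei_lr`: `network`, `rates` (tibble, Hz), `nu`
#'   (1/ms), `freq`, `C0` (n x nf baseline spectra), `A` (named list of
#'   n x nf complex susceptibility matrices), `ops` (operating points
#'   tibble), `spectra` (per-cell `ei_spectra` list).
#' @export
linear_response <- function(network, rates = NULL,
                            freq = lr_frequency_grid(), n_v = 2048) {
  stopifnot(inherits(network, "ei_network"))
  if (0 %in% freq == FALSE) freq <- c(0, freq)
  if (is.null(rates)) rates <- self_consistent_rates(network, n_v = n_v)
  ops <- cell_operating_points(network, rates$rate_hz)
  syn <- network$config$syn
  n <- nrow(ops)
  spectra <- lapply(seq_len(n), function(i) {
    cell_spectra(cell_point_from_row(ops[i, ], syn), freq = freq,
                 n_v = n_v)
  })
  nf <- length(freq)
  C0 <- t(vapply(spectra, function(s) s$C0, numeric(nf)))
  A <- lapply(fp_params, function(p) {
    t(vapply(spectra, function(s) s$A[, p], complex(nf)))
  })
  names(A) <- fp_params
  structure(list(network = network, rates = rates,
                 nu = vapply(spectra, function(s) s$nu, numeric(1)),
                 freq = freq, C0 = C0, A = A, ops = ops,
                 spectra = spectra),
            class = "ei_lr")
}

#' @export
print.ei_lr <- function(x, ...) {
  cat(sprintf(
    "<ei_lr> %d cells, %d frequencies; mean rates E %.2f Hz, I %.2f Hz\n",
    nrow(x$C0), length(x$freq),
    mean(x$rates$rate_hz[x$rates$type == "E"]),
    mean(x$rates$rate_hz[x$rates$type == "I"])))
  K0 <- interaction_matrix(x, 0)
  cat(sprintf("  spectral radius of K(0): %.3f\n",
              max(Mod(eigen(K0, only.values = TRUE)$values))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ei_lr <- function(x, ...) {
  i0 <- match(0, x$freq)
  dplyr::bind_cols(
    x$ops[, c("id", "type", "theta", "gE_mean", "gI_mean")],
    tibble::tibble(
      rate_hz = x$rates$rate_hz,
      C0_zero = x$C0[, i0],
      A_gE0 = Re(x$A$gE_mean[, i0]),
      A_gI0 = Re(x$A$gI_mean[, i0]),
      A_sigmaE2_0 = Re(x$A$sigmaE2[, i0]),
      A_sigmaI2_0 = Re(x$A$sigmaI2[, i0]),
      A_mu0 = Re(x$A$mu[, i0])
    ))
}

# Static edge-weight matrices for the interaction matrix: J carries the
# mean-conductance gain per unit presynaptic rate (amp * tau_r), L the
# conductance-variance gain (J * amp/2 * tau_r/(tau_r+tau_d)).
lr_edge_weights <- function(network) {
  type <- network$cells$type
  syn <- network$config$syn
  adj <- network$adjacency
  out <- list()
  for (x in c("E", "I")) {
    cols <- type == x
    ampx <- network$amp[cbind(type, x)] # per-target amplitude for X source
    J <- adj[, cols, drop = FALSE] * ampx * unname(syn$tau_r[x])
    L <- J * ampx / 2 * unname(syn$tau_r[x]) /
      (unname(syn$tau_r[x]) + unname(syn$tau_d[x]))
    out[[x]] <- list(J = J, L = L, cols = which(cols))
  }
  out
}

# interpolate stored complex susceptibilities / spectra onto new
# frequencies (natural splines of real and imaginary parts)
interp_rows <- function(M, freq, fout) {
  if (length(fout) == length(freq) && all(fout == freq)) return(M)
  t(apply(M, 1, function(y) {
    if (is.complex(y)) {
      complex(real = spline(freq, Re(y), xout = fout)$y,
              imaginary = spline(freq, Im(y), xout = fout)$y)
    } else spline(freq, y, xout = fout)$y
  }))
}

#' Interaction matrix at one frequency
#'
#' Assembles `K(f)`: for an excitatory source j,
#' `K_ij = A_gE,i(f) J_ij(f) + A_sigmaE2,i(f) L_ij(f)` and analogously
#' with the inhibitory susceptibilities for inhibitory sources, where
#' `J_ij` combines the edge conductance gain and the synaptic filter and
#' `L_ij` is its conductance-variance counterpart.  Inhibition enters
#' through the sign of `A_gI` (negative), not through signed weights.
#'
#' @param lr an [linear_response()] result.
#' @param f frequency in Hz (scalar).
#' @return Complex `n x n` matrix with the sparsity of the adjacency.
#' @export
interaction_matrix <- function(lr, f = 0) {
  stopifnot(inherits(lr, "ei_lr"), length(f) == 1)
  ew <- lr_edge_weights(lr$network)
  syn <- lr$network$config$syn
  Aat <- function(p) {
    i <- match(f, lr$freq)
    if (!is.na(i)) lr$A[[p]][, i]
    else as.vector(interp_rows(lr$A[[p]], lr$freq, f))
  }
  n <- nrow(lr$C0)
  K <- matrix(0i, n, n)
  for (x in c("E", "I")) {
    Ff <- synaptic_filter_ft(syn$tau_r[x], syn$tau_d[x], f)
    Ag <- Aat(if (x == "E") "gE_mean" else "gI_mean")
    As <- Aat(if (x == "E") "sigmaE2" else "sigmaI2")
    K[, ew[[x]]$cols] <- (Ag * ew[[x]]$J + As * ew[[x]]$L) * Ff
  }
  if (f == 0) K <- matrix(complex(real = Re(K)), n, n)
  K
}

#' Cross-spectral matrix at one frequency
#'
#' `C(f) = (I - K)^-1 C0 (I - K*)^-1`, Hermitian by construction.
#'
#' @param lr an [linear_response()] result.
#' @param f frequency in Hz (scalar).
#' @return Complex Hermitian `n x n` matrix (real at `f = 0`).
#' @export
cross_spectrum <- function(lr, f = 0) {
  K <- interaction_matrix(lr, f)
  n <- nrow(K)
  i <- match(f, lr$freq)
  C0 <- if (!is.na(i)) lr$C0[, i]
        else as.vector(interp_rows(lr$C0, lr$freq, f))
  IK <- diag(n) - K
  M <- tryCatch(solve(IK), error = function(e)
    stop("(I - K) is singular at f = ", f, " Hz"))
  Mc <- sweep(M, 2, C0, "*")
  Mc %*% Conj(t(M))
}

#' Windowed covariance and correlation from the linear-response spectrum
#'
#' Integrates the predicted cross-spectrum against the triangular-kernel
#' spectral window, `Cov_T = Int C(f) (sin(pi f T) / (pi f))^2 df`, on a
#' uniform fine frequency grid (susceptibilities interpolated from the
#' solver grid), handling the white high-frequency floor of the spectrum
#' diagonal analytically.  `T = Inf` returns the zero-frequency
#' correlations `C_ij(0) / sqrt(C_ii(0) C_jj(0))` directly.
#'
#' @param lr an [linear_response()] result.
#' @param windows count-window lengths in ms (may include `Inf`).
#' @param f_max,df integration grid (Hz); `df` should be well below `1/T`.
#' @return Object of class `ei_lr_correlations`: named lists `cov` and
#'   `rho` of matrices (one per window), the zero-frequency matrix
#'   `C0_matrix`, and a `pairs` tibble in wide format (one `rho_*` column
#'   per window) with linear-response rates.
#' @export
lr_correlations <- function(lr, windows = c(5, 50, 100, Inf),
                            f_max = 1000, df = 0.5) {
  stopifnot(inherits(lr, "ei_lr"))
  n <- nrow(lr$C0)
  fq <- seq(0, f_max, by = df)
  ew <- lr_edge_weights(lr$network)
  syn <- lr$network$config$syn
  Afine <- lapply(lr$A, interp_rows, freq = lr$freq, fout = fq)
  C0fine <- interp_rows(lr$C0, lr$freq, fq)
  FE <- synaptic_filter_ft(syn$tau_r["E"], syn$tau_d["E"], fq)
  FI <- synaptic_filter_ft(syn$tau_r["I"], syn$tau_d["I"], fq)
  finiteT <- windows[is.finite(windows)]
  acc <- lapply(finiteT, function(x) matrix(0, n, n))
  names(acc) <- as.character(finiteT)
  nu <- lr$nu
  Id <- diag(n)
  C0mat <- NULL
  df_khz <- df / 1000
  for (k in seq_along(fq)) {
    K <- matrix(0i, n, n)
    K[, ew$E$cols] <- (Afine$gE_mean[, k] * ew$E$J +
                         Afine$sigmaE2[, k] * ew$E$L) * FE[k]
    K[, ew$I$cols] <- (Afine$gI_mean[, k] * ew$I$J +
                         Afine$sigmaI2[, k] * ew$I$L) * FI[k]
    M <- solve(Id - K)
    C <- sweep(M, 2, C0fine[, k], "*") %*% Conj(t(M))
    Cr <- Re(C)
    if (k == 1) C0mat <- Cr
    diag(Cr) <- diag(Cr) - nu # white floor handled analytically
    f_khz <- fq[k] / 1000
    wtrapz <- if (k == 1 || k == length(fq)) 0.5 else 1
    for (Tc in names(acc)) {
      T <- as.numeric(Tc)
      w <- if (f_khz == 0) T^2 else (sin(pi * f_khz * T) / (pi * f_khz))^2
      acc[[Tc]] <- acc[[Tc]] + (2 * w * wtrapz * df_khz) * Cr
    }
  }
  cells <- lr$rates
  covs <- list(); rhos <- list()
  for (Tc in names(acc)) {
    T <- as.numeric(Tc)
    Cv <- acc[[Tc]] + diag(nu * T)
    v <- diag(Cv)
    if (any(v <= 0))
      stop("nonpositive predicted spike-count variance at T = ", Tc,
           " ms; refine the frequency grid")
    covs[[Tc]] <- Cv
    rhos[[Tc]] <- Cv / sqrt(outer(v, v))
  }
  if (any(is.infinite(windows))) {
    v0 <- diag(C0mat)
    if (any(v0 <= 0)) stop("nonpositive zero-frequency spectrum diagonal")
    rhos[["Inf"]] <- C0mat / sqrt(outer(v0, v0))
    covs[["Inf"]] <- C0mat
  }
  pairs <- pair_table(rhos[[1]], cells)
  pairs$rho <- NULL
  for (Tc in names(rhos)) pairs[[paste0("rho_", Tc)]] <- rhos[[Tc]][
    cbind(pairs$i, pairs$j)]
  structure(list(cov = covs, rho = rhos, C0_matrix = C0mat,
                 windows = windows, pairs = pairs, rates = cells),
            class = "ei_lr_correlations")
}

#' @exportS3Method generics::tidy
tidy.ei_lr_correlations <- function(x, ...) {
  tidyr::pivot_longer(x$pairs, dplyr::starts_with("rho_"),
                      names_to = "window", names_prefix = "rho_",
                      values_to = "rho")
}

#' @exportS3Method generics::glance
glance.ei_lr_correlations <- function(x, ...) {
  ee <- dplyr::filter(x$pairs, .data$type_i == "E", .data$type_j == "E")
  purrr::map_dfr(names(x$rho), function(Tc) {
    p <- ee
    p$rho <- ee[[paste0("rho_", Tc)]]
    fit <- corr_rate_regression(p)
    tibble::tibble(window = Tc, r_squared = fit$r_squared,
                   slope = fit$slope, mean_rho_EE = mean(p$rho))
  })
}
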