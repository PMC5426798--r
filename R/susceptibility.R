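#' Pairwise correlation susceptibility
#'
#' For each distinct E-E pair, the product of the two zero-frequency
#' single-cell susceptibilities over the geometric mean of the
#' zero-frequency spectra:
#' `S_ij = A_i(0) A_j(0) / sqrt(C_ii(0) C_jj(0))`, for modulation of
#' either the mean inhibitory conductance (`which = "gI"`) or the
#' effective input current (`which = "mu"`).  If `S_ij` increases with
#' firing rate across pairs, correlations from shared input will too.
#'
#' @param lr an [linear_response()] result.
#' @param which `"gI"` or `"mu"`.
#' @param C_diag diagonal of the zero-frequency cross-spectrum; defaults
#'   to the full linear-response prediction.
#' @return Tibble over distinct E-E pairs: `i`, `j`, `geom_rate`,
#'   `susceptibility`.
#' @export
pair_susceptibility <- function(lr, which = c("gI", "mu"),
                                C_diag = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(lr, "ei_lr"))
  if (is.null(C_diag)) C_diag <- Re(diag(cross_spectrum(lr, 0)))
  if (any(C_diag <= 0)) stop("nonpositive spectrum diagonal")
  par <- if (which == "gI") "gI_mean" else "mu"
  A0 <- Re(lr$A[[par]][, match(0, lr$freq)])
  type <- lr$network$cells$type
  ee <- which(type == "E")
  ij <- t(utils::combn(ee, 2))
  rates <- lr$rates$rate_hz
  tibble::tibble(
    i = ij[, 1], j = ij[, 2],
    geom_rate = sqrt(rates[ij[, 1]] * rates[ij[, 2]]),
    susceptibility = A0[ij[, 1]] * A0[ij[, 2]] /
      sqrt(C_diag[ij[, 1]] * C_diag[ij[, 2]])
  )
}

# population averages (over E cells) of the nuisance parameters
e_population_means <- function(lr) {
  opsE <- lr$ops[lr$network$cells$type == "E", ]
  list(sigmaI = mean(opsE$sigmaI), gE_mean = mean(opsE$gE_mean),
       sigmaE = mean(opsE$sigmaE), sigma = mean(opsE$sigma),
       gI_mean = mean(opsE$gI_mean))
}

# S = A_gI(0) / sqrt(nu): the per-cell factor whose pairwise product is
# the correlation susceptibility (rates in 1/ms)
susc_of <- function(res) {
  ifelse(res["nu", ] > 0, res["dnu", ] / sqrt(res["nu", ]), NA_real_)
}

# rate F (1/ms) and dF/d<gI> (= A_gI(0)) at one (gI, theta), with
# nuisance parameters fixed
rate_and_dgi <- function(gI, theta, nuis, syn, n_v = 2048) {
  pt <- operating_point(gE_mean = nuis$gE_mean, gI_mean = gI,
                        sigmaE = nuis$sigmaE, sigmaI = nuis$sigmaI,
                        sigma = nuis$sigma, theta = theta,
                        tau_m = syn$tau_m, tau_ref = syn$tau_ref,
                        E_E = unname(syn$reversal["E"]),
                        E_I = unname(syn$reversal["I"]))
  s <- fp_steady(pt, n_v)
  c(nu = s$nu, dnu = fp_susc0(pt, "gI_mean", steady = s))
}

#' Single-cell susceptibility to inhibitory-conductance fluctuations
#'
#' The single-cell quantity `S_i = A_gI,i(0) / sqrt(nu_i)` (negative in
#' the regimes studied here; its pairwise product is the correlation
#' susceptibility under the Poisson-variance assumption
#' `C_ii(0) = nu_i`) and its successive reductions:
#' \describe{
#'   \item{`full`}{evaluated at each cell's own six-parameter operating
#'     point.}
#'   \item{`averaged_nuisance`}{`sigma_I`, `<gE>`, `sigma_E` and `sigma`
#'     replaced by their E-population means, leaving `(<gI>, theta)`
#'     free: the two-parameter surface view.}
#'   \item{`averaged_gI`}{additionally replaces `<gI>` by its population
#'     mean, leaving only `theta_i`: the one-dimensional "path" the
#'     threshold-heterogeneous network takes through parameter space.}
#'   \item{`fixed_theta`}{a curve over `<gI>` at `theta = 1`: the
#'     alternative path generating rate diversity through inhibition
#'     rather than excitability.}
#' }
#'
#' @param lr an [linear_response()] result.
#' @param mode reduction mode (see above).
#' @param gI_range for `fixed_theta`: range of `<gI>` swept (defaults to
#'   the range realized in the network's E cells, widened by 20%).
#' @param n_points for `fixed_theta`: curve resolution.
#' @param n_v voltage grid points.
#' @return Tibble with `rate_hz` and `susceptibility` (plus `id`, `theta`
#'   for per-cell modes, `gI_mean` for the curve mode).  Cells with zero
#'   rate get `NA`.
#' @export
single_cell_susceptibility <- function(lr,
                                       mode = c("full", "averaged_nuisance",
                                                "averaged_gI",
                                                "fixed_theta"),
                                       gI_range = NULL, n_points = 41,
                                       n_v = 2048) {
  mode <- match.arg(mode)
  stopifnot(inherits(lr, "ei_lr"))
  syn <- lr$network$config$syn
  nuis <- e_population_means(lr)
  type <- lr$network$cells$type
  opsE <- lr$ops[type == "E", ]
  if (mode == "full") {
    i0 <- match(0, lr$freq)
    A0 <- Re(lr$A[["gI_mean"]][type == "E", i0])
    nu <- lr$nu[type == "E"]
    return(tibble::tibble(id = opsE$id, theta = opsE$theta,
                          rate_hz = 1000 * nu,
                          susceptibility = ifelse(nu > 0, A0 / sqrt(nu),
                                                  NA_real_)))
  }
  if (mode == "fixed_theta") {
    if (is.null(gI_range)) {
      r <- range(opsE$gI_mean)
      gI_range <- r + c(-0.2, 0.2) * diff(r)
    }
    gI <- seq(gI_range[1], gI_range[2], length.out = n_points)
    res <- vapply(gI, rate_and_dgi, numeric(2), theta = 1, nuis = nuis,
                  syn = syn, n_v = n_v)
    return(tibble::tibble(gI_mean = gI, rate_hz = 1000 * res["nu", ],
                          susceptibility = susc_of(res)))
  }
  gI <- if (mode == "averaged_gI") rep(nuis$gI_mean, nrow(opsE))
        else opsE$gI_mean
  res <- vapply(seq_len(nrow(opsE)), function(k) {
    rate_and_dgi(gI[k], opsE$theta[k], nuis, syn, n_v)
  }, numeric(2))
  tibble::tibble(id = opsE$id, theta = opsE$theta,
                 rate_hz = 1000 * res["nu", ],
                 susceptibility = susc_of(res))
}

#' Firing-rate and susceptibility surface over (<gI>, theta)
#'
#' Evaluates the reduced rate function `F(<gI>, theta)` (all nuisance
#' parameters at their E-population means) and the susceptibility
#' `S = (dF/d<gI>) / sqrt(F)` on a grid, for surface plots that show how
#' different paths through parameter space (the network's
#' threshold-diverse cells vs. an inhibition-diverse alternative) sample
#' different susceptibility landscapes.
#'
#' @param lr an [linear_response()] result.
#' @param gI_grid,theta_grid grid vectors; defaults span the network's E
#'   cells (gI widened 20%; theta over the threshold bounds).
#' @param n_v voltage grid points.
#' @return Object of class `ei_rate_surface`: `grid` tibble (`gI_mean`,
#'   `theta`, `rate_hz`, `susceptibility`), `cells` tibble of the actual
#'   (gI, theta) coordinates, and the `theta = 1` path.
#' @export
rate_surface <- function(lr, gI_grid = NULL, theta_grid = NULL,
                         n_v = 2048) {
  stopifnot(inherits(lr, "ei_lr"))
  syn <- lr$network$config$syn
  nuis <- e_population_means(lr)
  type <- lr$network$cells$type
  opsE <- lr$ops[type == "E", ]
  if (is.null(gI_grid)) {
    r <- range(opsE$gI_mean)
    gI_grid <- seq(r[1] - 0.2 * diff(r), r[2] + 0.2 * diff(r),
                   length.out = 25)
  }
  if (is.null(theta_grid)) {
    b <- lr$network$config$theta_bounds
    theta_grid <- seq(b[1], b[2], length.out = 25)
  }
  grid <- tidyr::expand_grid(gI_mean = gI_grid, theta = theta_grid)
  res <- vapply(seq_len(nrow(grid)), function(k) {
    rate_and_dgi(grid$gI_mean[k], grid$theta[k], nuis, syn, n_v)
  }, numeric(2))
  grid$rate_hz <- 1000 * res["nu", ]
  grid$susceptibility <- susc_of(res)
  cells <- tibble::tibble(id = opsE$id, gI_mean = opsE$gI_mean,
                          theta = opsE$theta,
                          rate_hz = lr$rates$rate_hz[type == "E"])
  structure(list(grid = grid, cells = cells,
                 theta1_path = dplyr::filter(
                   grid, abs(.data$theta - 1) ==
                     min(abs(theta_grid - 1)))),
            class = "ei_rate_surface")
}

#' @exportS3Method generics::tidy
tidy.ei_rate_surface <- function(x, ...) x$grid

#' Group E-E pairs by shared inhibitory input
#'
#' Counts, for every distinct E-E pair, the number of inhibitory cells
#' projecting to both, converts it to a common-input fraction
#' `c = n_shared / N_EI`, and attaches the pair's inhibitory-common-input
#' motif contribution and geometric-mean rate.  Within-group averages
#' expose the correlation-vs-c relationship conditioned on firing rate.
#'
#' @param motifs an [motif_decomposition()] (provides the network and the
#'   I-common contributions).
#' @return Tibble over distinct E-E pairs: `i`, `j`, `n_shared_I`, `c`,
#'   `geom_rate`, `rho_I_common` (normalized contribution), `total`.
#' @export
common_input_grouping <- function(motifs) {
  stopifnot(inherits(motifs, "ei_motifs"))
  net <- motifs$network
  type <- net$cells$type
  adjI <- net$adjacency[, type == "I", drop = FALSE]
  shared <- adjI %*% t(adjI) # (i, j): number of common I inputs
  N_EI <- net$config$N_in["E", "I"]
  pairs <- motifs$pairs
  ns <- shared[cbind(pairs$i, pairs$j)]
  tibble::tibble(
    i = pairs$i, j = pairs$j, n_shared_I = as.integer(ns),
    c = ns / N_EI, geom_rate = pairs$geom_rate,
    rho_I_common = pairs$common_I, total = pairs$total
  )
}
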