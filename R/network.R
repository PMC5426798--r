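#' Synapse constants shared by all cells
#'
#' Second-order alpha-synapse kinetics and reversal potentials.  All values
#' depend only on the type of the *source* neuron.  Units: times in ms,
#' reversal potentials in scaled voltage (rest = 0, homogeneous threshold
#' = 1).
#'
#' @return A list with named vectors `tau_r`, `tau_d`, `alpha`, `reversal`
#'   (each with elements `E` and `I`) plus scalars `tau_m` and `tau_ref`.
#' @export
synapse_constants <- function() {
  list(
    tau_r    = c(E = 1,   I = 2),
    tau_d    = c(E = 5,   I = 10),
    alpha    = c(E = 1,   I = 2),
    reversal = c(E = 6.5, I = -0.5),
    tau_m    = 20,
    tau_ref  = 2
  )
}

#' Network configuration for a firing regime
#'
#' Assembles the full configuration of a recurrent E/I network: population
#' sizes, raw synaptic weights `W[target_type, source_type]`, in-degrees,
#' background-noise magnitudes and threshold heterogeneity.  Two presets
#' are provided.  In the `"asynchronous"` regime recurrent excitation is
#' weak and spiking is Poisson-like with flat population spectra; the
#' `"strong_asynchronous"` regime increases both W_EE and W_IE, producing
#' occasional partial-population bursts and a weak ~8 Hz spectral maximum.
#'
#' The raw weight of an X -> Y connection is divided by the in-degree
#' N_YX, so each delivered conductance pulse has amplitude
#' `alpha_X * W[Y,X] / N_in[Y,X]`.
#'
#' The background-noise magnitudes default to sigma_E = 2/sqrt(2), sigma_I
#' = 3/sqrt(2) (asynchronous) and 1.5/sqrt(2), 2.5/sqrt(2) (strong
#' asynchronous); they are exposed here because the defaults are a reading
#' of an ambiguously typeset table (see the methods vignette) and users may
#' wish to override them.
#'
#' @param regime `"asynchronous"`, `"strong_asynchronous"`, or `"custom"`
#'   (with `W` and `sigma` supplied explicitly).
#' @param n_E,n_I population sizes (defaults 80/20).
#' @param s_theta spread of the threshold distribution (0 = homogeneous).
#' @param topology `"fixed_in_degree"` (each cell receives exactly
#'   `N_in[Y,X]` type-X inputs) or `"erdos_renyi"` (each potential edge
#'   drawn independently with probability `p_conn[Y,X]`).
#' @param W optional 2x2 weight matrix (rows = target type E/I, columns =
#'   source type E/I), required for `regime = "custom"`.
#' @param sigma optional named numeric `c(E = , I = )` of background-noise
#'   magnitudes, overriding the regime preset.
#' @param p_conn optional 2x2 connection-probability matrix; defaults to
#'   40% E->E, 35% I->E, 20% E->I, 40% I->I.
#' @param theta_bounds truncation interval for thresholds.
#' @return An object of class `ei_network_config`.
#' @export
ei_network_config <- function(regime = c("asynchronous",
                                         "strong_asynchronous", "custom"),
                              n_E = 80, n_I = 20, s_theta = 0.2,
                              topology = c("fixed_in_degree", "erdos_renyi"),
                              W = NULL, sigma = NULL, p_conn = NULL,
                              theta_bounds = c(0.7, 1.4)) {
  regime <- match.arg(regime)
  topology <- match.arg(topology)
  tt <- c("E", "I")
  if (is.null(p_conn)) {
    p_conn <- matrix(c(0.40, 0.20, 0.35, 0.40), 2, 2,
                     dimnames = list(target = tt, source = tt))
  }
  presets <- list(
    asynchronous = list(
      W = matrix(c(0.5, 5, 10, 5), 2, 2,
                 dimnames = list(target = tt, source = tt)),
      sigma = c(E = 2 / sqrt(2), I = 3 / sqrt(2))
    ),
    strong_asynchronous = list(
      W = matrix(c(9, 8, 10, 5), 2, 2,
                 dimnames = list(target = tt, source = tt)),
      sigma = c(E = 1.5 / sqrt(2), I = 2.5 / sqrt(2))
    )
  )
  if (regime == "custom") {
    if (is.null(W) || is.null(sigma))
      stop("custom regime requires explicit `W` and `sigma`")
  } else {
    if (is.null(W)) W <- presets[[regime]]$W
    if (is.null(sigma)) sigma <- presets[[regime]]$sigma
  }
  stopifnot(all(W >= 0), all(sigma > 0), n_E + n_I >= 2)
  n_src <- c(E = n_E, I = n_I)
  N_in <- round(p_conn * rep(n_src, each = 2))
  storage.mode(N_in) <- "integer"
  for (y in tt) for (x in tt) {
    if (N_in[y, x] > n_src[x])
      stop("in-degree N_", y, x, " exceeds the available source pool")
  }
  structure(list(regime = regime, n_E = n_E, n_I = n_I,
                 W = W, p_conn = p_conn, N_in = N_in, sigma = sigma,
                 s_theta = s_theta, topology = topology,
                 theta_bounds = theta_bounds,
                 syn = synapse_constants()),
            class = "ei_network_config")
}

#' Draw a random connectivity matrix
#'
#' Builds the binary directed adjacency matrix (entry `(i, j) = 1` iff
#' `j -> i`).  Under the fixed in-degree topology each target draws exactly
#' `N_in[Y,X]` type-X sources uniformly without replacement (targets are
#' processed in index order, excitatory sources drawn before inhibitory,
#' so a seed fully determines the graph).  Under the Erdos-Renyi topology
#' each potential edge is an independent Bernoulli draw with the
#' type-pair connection probability.  No self-edges in either mode.
#'
#' @param config an [ei_network_config()].
#' @param rng_seed integer seed (or `NULL` to use the session RNG stream).
#' @return An `n x n` integer matrix, `n = n_E + n_I`; cells `1..n_E` are
#'   excitatory.
#' @export
build_connectivity <- function(config, rng_seed = NULL) {
  stopifnot(inherits(config, "ei_network_config"))
  n <- config$n_E + config$n_I
  type <- cell_types(config)
  adj <- matrix(0L, n, n)
  with_seed(rng_seed, {
    if (config$topology == "fixed_in_degree") {
      src_pool <- list(E = which(type == "E"), I = which(type == "I"))
      for (i in seq_len(n)) {
        y <- type[i]
        for (x in c("E", "I")) {
          pool <- setdiff(src_pool[[x]], i)
          k <- config$N_in[y, x]
          if (k > length(pool))
            stop("in-degree exceeds eligible source pool for cell ", i)
          if (k > 0) adj[i, sample(pool, k)] <- 1L
        }
      }
    } else {
      p <- matrix(0, n, n)
      for (y in c("E", "I")) for (x in c("E", "I")) {
        p[type == y, type == x] <- config$p_conn[y, x]
      }
      adj <- matrix(as.integer(runif(n * n) < p), n, n)
      diag(adj) <- 0L
    }
  })
  adj
}

#' Sample heterogeneous spiking thresholds
#'
#' Thresholds are lognormal: `log(theta) ~ Normal(-s_theta^2/2, s_theta^2)`
#' truncated to `[log(bounds[1]), log(bounds[2])]`, so that the
#' *untruncated* distribution has mean exactly 1 and variance
#' `exp(s_theta^2) - 1`.  Sampling is by rejection (exact); the acceptance
#' rate is recorded in the `"acceptance_rate"` attribute.
#'
#' @param n number of thresholds.
#' @param s_theta spread; `0` returns a vector of exact 1s.
#' @param bounds truncation interval (default `c(0.7, 1.4)`).
#' @param rng_seed integer seed or `NULL`.
#' @return Numeric vector of thresholds in `bounds`.
#' @export
sample_thresholds <- function(n, s_theta = 0.2, bounds = c(0.7, 1.4),
                              rng_seed = NULL) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2], bounds[1] > 0,
            s_theta >= 0, n >= 0)
  if (s_theta == 0) return(rep(1, n))
  lo <- log(bounds[1]); hi <- log(bounds[2])
  mu <- -s_theta^2 / 2
  out <- numeric(0)
  tries <- 0L
  with_seed(rng_seed, {
    while (length(out) < n) {
      draw <- rnorm(max(2L * (n - length(out)), 16L), mu, s_theta)
      tries <- tries + length(draw)
      out <- c(out, draw[draw >= lo & draw <= hi])
    }
  })
  structure(exp(out[seq_len(n)]),
            acceptance_rate = length(out) / tries)
}

cell_types <- function(config) {
  c(rep("E", config$n_E), rep("I", config$n_I))
}

#' Build a recurrent E/I network
#'
#' Generates connectivity and per-cell parameters for one network
#' realization: the synthetic-data generator that every other stage of the
#' package consumes.
#'
#' @param regime preset name, or an [ei_network_config()] object.
#' @param heterogeneous if `TRUE` thresholds are sampled from the truncated
#'   lognormal; if `FALSE` every threshold is exactly 1.
#' @param rng_seed integer seed making the network reproducible
#'   (connectivity is drawn first, thresholds second, from one stream).
#' @param ... passed to [ei_network_config()] when `regime` is a name.
#' @return An object of class `ei_network` with elements `adjacency`
#'   (binary matrix, `(i,j)=1` iff `j -> i`), `amp` (2x2 matrix of
#'   per-edge pulse amplitudes `alpha_X W_YX / N_YX` by target/source
#'   type), `cells` (tibble: id, type, theta, sigma), and `config`.
#' @examples
#' net <- ei_network("asynchronous", rng_seed = 1)
#' net
#' @export
ei_network <- function(regime = "asynchronous", heterogeneous = TRUE,
                       rng_seed = NULL, ...) {
  config <- if (inherits(regime, "ei_network_config")) regime
            else ei_network_config(regime, ...)
  if (!heterogeneous) config$s_theta <- 0
  n <- config$n_E + config$n_I
  type <- cell_types(config)
  adj <- NULL; theta <- NULL
  with_seed(rng_seed, {
    adj <- build_connectivity(config, rng_seed = NULL)
    theta <- sample_thresholds(n, config$s_theta, config$theta_bounds,
                               rng_seed = NULL)
  })
  # per-edge pulse amplitude by (target type, source type); under the
  # Erdos-Renyi topology the divisor is the expected in-degree so the
  # synaptic scale is identical across cells
  divisor <- config$N_in
  amp <- config$syn$alpha[col(divisor)] * config$W / divisor
  dimnames(amp) <- dimnames(config$W)
  cells <- tibble::tibble(
    id = seq_len(n), type = type, theta = as.numeric(theta),
    sigma = unname(config$sigma[type])
  )
  structure(list(adjacency = adj, amp = amp, cells = cells,
                 config = config, rng_seed = rng_seed),
            class = "ei_network")
}

#' @export
print.ei_network <- function(x, ...) {
  cfg <- x$config
  cat("<ei_network> ", cfg$regime, " regime, ",
      cfg$n_E, " E + ", cfg$n_I, " I cells, ",
      sum(x$adjacency), " edges (", cfg$topology, ")\n", sep = "")
  cat("  thresholds: ",
      if (cfg$s_theta > 0) {
        sprintf("heterogeneous (s_theta = %g, range %.3f-%.3f)",
                cfg$s_theta, min(x$cells$theta), max(x$cells$theta))
      } else "homogeneous (theta = 1)", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ei_network <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  type <- x$cells$type
  tibble::tibble(
    source = idx[, 2], target = idx[, 1],
    source_type = type[idx[, 2]], target_type = type[idx[, 1]],
    amplitude = x$amp[cbind(type[idx[, 1]], type[idx[, 2]])]
  ) |> dplyr::arrange(.data$source, .data$target)
}

#' Write / read a network archive
#'
#' Serializes a network as a directory of plain-text files: `edges.csv`
#' (source, target, amplitude), `cells.csv` (id, type, theta, sigma) and
#' `config.json`.
#'
#' @param network an [ei_network()].
#' @param path directory to create/overwrite.
#' @return `write_ei_network()` returns `path` invisibly;
#'   `read_ei_network()` returns the reconstructed `ei_network`.
#' @export
write_ei_network <- function(network, path) {
  stopifnot(inherits(network, "ei_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  edges <- tidy(network)
  write.csv(edges, file.path(path, "edges.csv"), row.names = FALSE)
  write.csv(network$cells, file.path(path, "cells.csv"), row.names = FALSE)
  cfg <- network$config
  jsonlite::write_json(
    list(regime = cfg$regime, n_E = cfg$n_E, n_I = cfg$n_I,
         W = cfg$W, p_conn = cfg$p_conn, N_in = cfg$N_in,
         sigma = as.list(cfg$sigma), s_theta = cfg$s_theta,
         topology = cfg$topology, theta_bounds = cfg$theta_bounds,
         rng_seed = network$rng_seed),
    file.path(path, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ei_network
#' @export
read_ei_network <- function(path) {
  cfg <- jsonlite::read_json(file.path(path, "config.json"),
                             simplifyVector = TRUE)
  config <- ei_network_config(
    regime = cfg$regime, n_E = cfg$n_E, n_I = cfg$n_I,
    s_theta = cfg$s_theta, topology = cfg$topology,
    W = matrix(unlist(cfg$W), 2, 2,
               dimnames = list(target = c("E", "I"), source = c("E", "I"))),
    sigma = unlist(cfg$sigma),
    p_conn = matrix(unlist(cfg$p_conn), 2, 2,
                    dimnames = list(target = c("E", "I"),
                                    source = c("E", "I"))),
    theta_bounds = unlist(cfg$theta_bounds))
  config$regime <- cfg$regime
  cells <- tibble::as_tibble(read.csv(file.path(path, "cells.csv"),
                                      stringsAsFactors = FALSE))
  edges <- read.csv(file.path(path, "edges.csv"))
  n <- nrow(cells)
  adj <- matrix(0L, n, n)
  adj[cbind(edges$target, edges$source)] <- 1L
  divisor <- config$N_in
  amp <- config$syn$alpha[col(divisor)] * config$W / divisor
  dimnames(amp) <- dimnames(config$W)
  structure(list(adjacency = adj, amp = amp, cells = cells,
                 config = config, rng_seed = cfg$rng_seed),
            class = "ei_network")
}
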