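#' Simulation configuration
#'
#' @param duration per-realization simulated time after equilibration (ms).
#' @param n_realizations number of independent realizations.
#' @param dt Euler-Maruyama step (ms); must satisfy
#'   `dt <= 0.01 * min(tau_r)` or a warning is issued.
#' @param equilibration discarded transient per realization (ms).
#' @param bin_width spike-count bin (ms); must be an integer multiple of
#'   `dt` and divide `duration`.
#' @param seed integer seed for the simulator's own RNG stream.
#' @return A list of class `ei_sim_config`.
#' @export
sim_config <- function(duration = 1000, n_realizations = 1, dt = 0.01,
                       equilibration = 1000, bin_width = 1, seed = 1) {
  stopifnot(duration > 0, n_realizations >= 1, dt > 0,
            equilibration >= 0, bin_width > 0)
  if (abs(bin_width / dt - round(bin_width / dt)) > 1e-9)
    stop("bin_width must be an integer multiple of dt")
  if (abs(duration / bin_width - round(duration / bin_width)) > 1e-9)
    stop("duration must be an integer multiple of bin_width")
  structure(list(duration = duration, n_realizations = n_realizations,
                 dt = dt, equilibration = equilibration,
                 bin_width = bin_width, seed = seed),
            class = "ei_sim_config")
}

#' Monte-Carlo simulation of the network
#'
#' Euler-Maruyama integration of the coupled conductance-based LIF
#' network.  On a threshold crossing the spike is recorded at the end of
#' the crossing step, the auxiliary conductance of every postsynaptic
#' target jumps by the edge amplitude, and the voltage is held for
#' `tau_ref` before release at the reset potential 0.  Each realization
#' starts from rest, is equilibrated, and spike counts are retained in
#' `bin_width` bins.
#'
#' @param network an [ei_network()].
#' @param sim an [sim_config()].
#' @return An object of class `ei_spike_counts`: integer `counts` matrix
#'   (cells x bins, realizations concatenated), `bin_width`, `duration`,
#'   `n_realizations`, and a `rates` tibble (Hz).
#' @export
simulate_network <- function(network, sim = sim_config()) {
  stopifnot(inherits(network, "ei_network"), inherits(sim, "ei_sim_config"))
  syn <- network$config$syn
  if (sim$dt > 0.01 * min(syn$tau_r))
    warning("dt is large relative to the synaptic rise times; ",
            "rates may not be converged")
  cells <- network$cells
  type01 <- as.integer(cells$type == "I")
  # CSR by source: targets of each source, with per-edge amplitudes
  adj <- network$adjacency
  idx <- which(adj == 1L, arr.ind = TRUE) # (target, source)
  o <- order(idx[, 2], idx[, 1])
  tgt <- idx[o, 1] - 1L
  src <- idx[o, 2]
  ptr <- c(0L, cumsum(tabulate(src, nbins = nrow(cells))))
  amp <- network$amp[cbind(cells$type[idx[o, 1]], cells$type[src])]
  res <- sim_network_cpp(
    cell_type = type01, theta = cells$theta, sigma = cells$sigma,
    tau_m = syn$tau_m, tau_ref = syn$tau_ref,
    tau_r = unname(syn$tau_r), tau_d = unname(syn$tau_d),
    E_E = unname(syn$reversal["E"]), E_I = unname(syn$reversal["I"]),
    src_ptr = ptr, tgt = tgt, amp = amp,
    dt = sim$dt, steps_per_real = as.integer(round(sim$duration / sim$dt)),
    equil_steps = as.integer(round(sim$equilibration / sim$dt)),
    n_real = sim$n_realizations,
    bin_steps = as.integer(round(sim$bin_width / sim$dt)),
    seed = sim$seed)
  total_ms <- sim$duration * sim$n_realizations
  rates <- dplyr::bind_cols(
    cells[, c("id", "type", "theta")],
    tibble::tibble(rate_hz = 1000 * res$spikes_total / total_ms))
  structure(list(counts = res$counts, bin_width = sim$bin_width,
                 duration = sim$duration,
                 n_realizations = sim$n_realizations,
                 cells = cells, rates = rates, sim = sim),
            class = "ei_spike_counts")
}

#' @export
print.ei_spike_counts <- function(x, ...) {
  cat(sprintf(
    "<ei_spike_counts> %d cells, %d x %g ms, %g ms bins\n",
    nrow(x$counts), x$n_realizations, x$duration, x$bin_width))
  cat(sprintf("  mean rates: E %.2f Hz, I %.2f Hz\n",
              mean(x$rates$rate_hz[x$rates$type == "E"]),
              mean(x$rates$rate_hz[x$rates$type == "I"])))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ei_spike_counts <- function(x, ...) x$rates

# Re-bin counts to windows of T ms; returns (windows x cells) matrix,
# windows never spanning realization boundaries.
rebin_counts <- function(counts_obj, T) {
  r <- T / counts_obj$bin_width
  if (abs(r - round(r)) > 1e-9)
    stop("window T must be an integer multiple of the stored bin width")
  r <- as.integer(round(r))
  cnt <- counts_obj$counts # cells x total bins
  nb <- ncol(cnt)
  nwin <- nb %/% r
  per_real <- as.integer(round(counts_obj$duration / counts_obj$bin_width))
  if (per_real %% r != 0)
    stop("window T must divide the realization duration")
  grp <- rep(seq_len(nwin), each = r)
  # sum consecutive groups of r bins
  X <- t(rowsum(t(cnt), grp, reorder = FALSE))
  t(X) # windows x cells
}

#' Windowed spike-count statistics
#'
#' Re-bins counts to windows of length `T`, then computes per-cell rate
#' and Fano factor and the pairwise Pearson spike-count correlation matrix
#' across all windows and realizations.
#'
#' @param counts an `ei_spike_counts` from [simulate_network()].
#' @param T window length (ms); integer multiple of the stored bin width,
#'   dividing the realization duration.
#' @return List of class `ei_count_stats`: `cells` tibble (id, type, rate
#'   in Hz, `fano`), `rho` (correlation matrix, `NA` for zero-variance
#'   cells), `cov` (covariance per window), `T`, and `pairs` tibble of
#'   distinct pairs with geometric-mean rates.
#' @export
spike_count_stats <- function(counts, T = 100) {
  X <- rebin_counts(counts, T)
  m <- colMeans(X)
  v <- apply(X, 2, var)
  fano <- ifelse(m > 0, v / m, NA_real_)
  zero <- v <= 0
  rho <- suppressWarnings(cor(X))
  rho[zero, ] <- NA_real_
  rho[, zero] <- NA_real_
  diag(rho)[!zero] <- 1
  if (any(zero))
    message(sum(zero), " cell(s) with zero count variance; ",
            "correlations reported as NA")
  cells <- dplyr::bind_cols(
    counts$cells[, c("id", "type", "theta")],
    tibble::tibble(rate_hz = 1000 * m / T, fano = fano))
  pairs <- pair_table(rho, cells)
  structure(list(cells = cells, rho = rho, cov = cov(X), T = T,
                 pairs = pairs),
            class = "ei_count_stats")
}

# long-format table of distinct pairs (i < j) with rates and correlation
pair_table <- function(rho, cells) {
  n <- nrow(rho)
  ij <- which(upper.tri(rho), arr.ind = TRUE)
  tibble::tibble(
    i = ij[, 1], j = ij[, 2],
    type_i = cells$type[ij[, 1]], type_j = cells$type[ij[, 2]],
    rate_i = cells$rate_hz[ij[, 1]], rate_j = cells$rate_hz[ij[, 2]],
    geom_rate = sqrt(cells$rate_hz[ij[, 1]] * cells$rate_hz[ij[, 2]]),
    rho = rho[ij]
  )
}

#' @exportS3Method generics::tidy
tidy.ei_count_stats <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.ei_count_stats <- function(x, ...) {
  ee <- dplyr::filter(x$pairs, .data$type_i == "E", .data$type_j == "E")
  fit <- corr_rate_regression(ee)
  tibble::tibble(
    T = x$T,
    mean_rate_E = mean(x$cells$rate_hz[x$cells$type == "E"]),
    mean_rate_I = mean(x$cells$rate_hz[x$cells$type == "I"]),
    mean_fano = mean(x$cells$fano, na.rm = TRUE),
    max_fano = max(x$cells$fano, na.rm = TRUE),
    mean_rho_EE = mean(ee$rho, na.rm = TRUE),
    r_squared = fit$r_squared
  )
}

#' Regression of pairwise correlation on geometric-mean rate
#'
#' Ordinary least squares (with intercept) of `rho` on
#' `sqrt(rate_i * rate_j)` across pairs; the R^2 of this regression is the
#' package's standard measure of a correlation-firing rate relationship.
#'
#' @param pairs tibble with columns `rho` and `geom_rate` (e.g. the E-E
#'   subset of `tidy(spike_count_stats(...))`).
#' @return List with `r_squared`, `slope`, `intercept`, `n`.
#' @export
corr_rate_regression <- function(pairs) {
  ok <- complete.cases(pairs[, c("rho", "geom_rate")])
  x <- pairs$geom_rate[ok]; y <- pairs$rho[ok]
  stopifnot(length(x) >= 3)
  fit <- lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' Correlation-rate regression R-squared from spike counts
#'
#' Computes the OLS R^2 of E-E spike-count correlation against
#' geometric-mean firing rate at window `T`, optionally disattenuated
#' for the finite-sampling noise of each Pearson coefficient.  At finite
#' simulated time the per-pair correlation estimates carry estimation
#' noise that inflates the outcome variance and biases the raw R^2
#' downward; the corrected value divides by the Spearman-Brown
#' reliability estimated from two independent halves of the data (split
#' by realization when possible, by time otherwise), and estimates the
#' infinite-data R^2.
#'
#' @param counts an `ei_spike_counts` from [simulate_network()].
#' @param T window length (ms).
#' @return List with `raw`, `reliability` (split-half, full length) and
#'   `corrected` (capped at 1; equals `raw` when the reliability cannot
#'   be estimated or is nonpositive).
#' @export
corr_rate_r2 <- function(counts, T = 5) {
  st <- spike_count_stats(counts, T = T)
  ee <- dplyr::filter(st$pairs, .data$type_i == "E",
                      .data$type_j == "E", !is.na(.data$rho))
  raw <- corr_rate_regression(ee)$r_squared
  half <- function(idx, per) {
    obj <- counts
    cols <- as.vector(vapply(idx, function(r) ((r - 1) * per + 1):(r * per),
                             numeric(per)))
    obj$counts <- counts$counts[, cols, drop = FALSE]
    obj
  }
  per <- as.integer(round(counts$duration / counts$bin_width))
  if (counts$n_realizations >= 2) {
    k <- counts$n_realizations
    h1 <- half(seq_len(k %/% 2), per)
    h1$n_realizations <- k %/% 2
    h2 <- half((k %/% 2 + 1):k, per)
    h2$n_realizations <- k - k %/% 2
  } else {
    # single realization: contiguous time halves
    h1 <- counts; h2 <- counts
    h1$counts <- counts$counts[, 1:(per %/% 2), drop = FALSE]
    h1$duration <- (per %/% 2) * counts$bin_width
    h2$counts <- counts$counts[, (per %/% 2 + 1):per, drop = FALSE]
    h2$duration <- (per - per %/% 2) * counts$bin_width
  }
  s1 <- spike_count_stats(h1, T = T)
  s2 <- spike_count_stats(h2, T = T)
  ij <- cbind(ee$i, ee$j)
  rel_half <- suppressWarnings(cor(s1$rho[ij], s2$rho[ij],
                                   use = "complete.obs"))
  if (!is.finite(rel_half) || rel_half <= 0) {
    return(list(raw = raw, reliability = NA_real_, corrected = raw))
  }
  rel <- 2 * rel_half / (1 + rel_half)
  list(raw = raw, reliability = rel, corrected = min(raw / rel, 1))
}

#' Population power spectrum of the summed spike counts
#'
#' Mean-subtracted population-summed spike counts of one cell type,
#' averaged periodogram over realizations and non-overlapping segments,
#' normalized to the maximum and expressed in dB.
#'
#' @param counts an `ei_spike_counts`.
#' @param cell_type `"E"` or `"I"`.
#' @param segment_ms periodogram segment length (ms); default 1024 bins
#'   worth, giving ~1 Hz resolution at 1 ms bins.
#' @return Tibble with `freq` (Hz), `power` (linear, per Hz) and
#'   `power_db` (10 log10, max = 0 dB).
#' @export
population_power_spectrum <- function(counts, cell_type = "E",
                                      segment_ms = NULL) {
  sel <- counts$cells$type == cell_type
  pop <- colSums(counts$counts[sel, , drop = FALSE])
  per_real <- as.integer(round(counts$duration / counts$bin_width))
  if (is.null(segment_ms)) segment_ms <- min(1024 * counts$bin_width,
                                             counts$duration)
  L <- as.integer(round(segment_ms / counts$bin_width))
  stopifnot(L >= 8, per_real >= L)
  nseg_per_real <- per_real %/% L
  acc <- NULL
  for (r in seq_len(counts$n_realizations)) {
    off <- (r - 1L) * per_real
    for (s in seq_len(nseg_per_real)) {
      seg <- pop[off + ((s - 1L) * L + 1L):(s * L)]
      seg <- seg - mean(seg)
      pg <- Mod(fft(seg))^2 / L
      acc <- if (is.null(acc)) pg else acc + pg
    }
  }
  acc <- acc / (counts$n_realizations * nseg_per_real)
  keep <- 2:(L %/% 2) # drop DC and aliased upper half
  freq <- (keep - 1) / (L * counts$bin_width) * 1000
  p <- acc[keep]
  tibble::tibble(freq = freq, power = p,
                 power_db = 10 * log10(p / max(p)))
}
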