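#' Contribution of length-n paths to the cross-spectrum
#'
#' In the series expansion of `(I-K)^-1 C0 (I-K*)^-1`, the order-n piece
#' is `P^n = sum_{l=0..n} K^(n-l) C0 (K*)^l`: all undirected paths of
#' total length n connecting the pair (chains and common-input
#' subgraphs).
#'
#' @param K interaction matrix at one frequency (typically `f = 0`).
#' @param C0 vector of baseline power spectra (diagonal of `C0`).
#' @param n path order (`0` returns `diag(C0)` itself).
#' @return Matrix of the same type as `K`.
#' @export
motif_order_contribution <- function(K, C0, n) {
  stopifnot(n >= 0, nrow(K) == length(C0))
  rho <- max(Mod(eigen(K, only.values = TRUE)$values))
  if (rho >= 1)
    stop("spectral radius of K is ", round(rho, 3),
         " >= 1; the motif series diverges")
  C0d <- diag(C0)
  acc <- matrix(0, nrow(K), ncol(K))
  Kh <- Conj(t(K))
  for (l in 0:n) {
    left <- if (n - l == 0) C0d else mat_pow(K, n - l) %*% C0d
    acc <- acc + (if (l == 0) left else left %*% mat_pow(Kh, l))
  }
  acc
}

mat_pow <- function(M, p) {
  out <- M
  if (p > 1) for (k in 2:p) out <- out %*% M
  out
}

#' Normalize a path contribution by the total spectrum diagonal
#'
#' `R^n_ij = P^n_ij / sqrt(C_ii C_jj)` with `C` the *full* predicted
#' cross-spectrum; summed over all orders this recovers the long-window
#' correlation coefficient.
#'
#' @param P contribution matrix.
#' @param C_diag diagonal of the full cross-spectrum at the same
#'   frequency (must be strictly positive).
#' @return Matrix of normalized contributions.
#' @export
normalize_contribution <- function(P, C_diag) {
  if (any(Re(C_diag) <= 0)) stop("nonpositive spectrum diagonal")
  s <- 1 / sqrt(Re(C_diag))
  P * outer(s, s)
}

#' Motif decomposition of the predicted correlations
#'
#' Decomposes the zero-frequency linear-response correlation matrix into
#' path-order contributions `R^1 ... R^n_max` and splits the second order
#' by the type of the intermediate cell: chains through an E or I cell
#' (`K^2 C0` and its transpose, restricted over the middle index) and
#' common input from an E or I source (`K C0 K*`, restricted over the
#' source index).
#'
#' @param lr an [linear_response()] result.
#' @param n_max largest path order retained (default 6).
#' @param f frequency in Hz (default 0 = long-timescale correlations).
#' @return Object of class `ei_motifs`: `K`, `C0`, `C_full`, `total`
#'   (normalized correlation matrix), `R` (list of normalized order
#'   contributions), `P` (raw contributions), `by_type` (normalized
#'   second-order motif matrices `chain_E`, `chain_I`, `common_E`,
#'   `common_I`), `spectral_radius`, and a `pairs` tibble over distinct
#'   E-E pairs.
#' @export
motif_decomposition <- function(lr, n_max = 6, f = 0) {
  stopifnot(inherits(lr, "ei_lr"))
  K <- interaction_matrix(lr, f)
  if (f == 0) K <- Re(K)
  i0 <- match(f, lr$freq)
  C0 <- if (!is.na(i0)) lr$C0[, i0]
        else as.vector(interp_rows(lr$C0, lr$freq, f))
  rho_K <- max(Mod(eigen(K, only.values = TRUE)$values))
  if (rho_K >= 1)
    stop("spectral radius of K is ", round(rho_K, 3), " >= 1")
  n <- nrow(K)
  Cfull <- cross_spectrum(lr, f)
  if (f == 0) Cfull <- Re(Cfull)
  Cdiag <- Re(diag(Cfull))
  total <- normalize_contribution(Cfull, Cdiag)
  P <- lapply(0:n_max, function(k) motif_order_contribution(K, C0, k))
  names(P) <- as.character(0:n_max)
  R <- lapply(P, normalize_contribution, C_diag = Cdiag)
  # second order by intermediate-cell type
  type <- lr$network$cells$type
  by_type <- list()
  Kh <- Conj(t(K))
  for (x in c("E", "I")) {
    cols <- type == x
    Kx <- K[, cols, drop = FALSE]
    chain <- Kx %*% K[cols, , drop = FALSE] %*% diag(C0)
    chain <- chain + Conj(t(chain))
    common <- Kx %*% diag(C0[cols]) %*% Conj(t(Kx))
    by_type[[paste0("chain_", x)]] <- normalize_contribution(chain, Cdiag)
    by_type[[paste0("common_", x)]] <- normalize_contribution(common, Cdiag)
  }
  ee <- which(type == "E")
  ij <- t(utils::combn(ee, 2))
  rates <- lr$rates$rate_hz
  pairs <- tibble::tibble(
    i = ij[, 1], j = ij[, 2],
    rate_i = rates[ij[, 1]], rate_j = rates[ij[, 2]],
    geom_rate = sqrt(rates[ij[, 1]] * rates[ij[, 2]]),
    total = Re(total[ij]))
  for (k in seq_len(n_max)) pairs[[paste0("R", k)]] <- Re(R[[k + 1]][ij])
  for (nm in names(by_type)) pairs[[nm]] <- Re(by_type[[nm]][ij])
  structure(list(K = K, C0 = C0, C_full = Cfull, total = total,
                 P = P, R = R, by_type = by_type,
                 spectral_radius = rho_K, n_max = n_max, f = f,
                 pairs = pairs, network = lr$network),
            class = "ei_motifs")
}

#' @export
print.ei_motifs <- function(x, ...) {
  cat(sprintf(
    "<ei_motifs> orders 0-%d at f = %g Hz; spectral radius %.3f\n",
    x$n_max, x$f, x$spectral_radius))
  print(motif_regression_stats(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ei_motifs <- function(x, ...) x$pairs

#' Regression and fraction statistics of the motif decomposition
#'
#' For each path order, the R^2 from a simple OLS regression (with
#' intercept) of total normalized correlation on that order's
#' contribution across distinct E-E pairs; optionally, the mean fraction
#' of the total contributed by each order.  The fraction measure requires
#' (essentially) positive totals: pairs with `total <= 0` are dropped
#' with a message, and if more than `max_nonpositive` of pairs are
#' nonpositive the fraction is refused (as in the asynchronous regime,
#' where contributions of alternating sign make it meaningless).
#'
#' @param motifs an [motif_decomposition()] (or its `pairs` tibble).
#' @param fractions compute the fraction-of-total column?
#' @param max_nonpositive largest tolerable share of nonpositive totals.
#' @return Tibble with one row per order (`r_squared`, optionally
#'   `fraction`) and one row per second-order motif type (`r_squared` of
#'   total second-order contribution on that motif's contribution).
#' @export
motif_regression_stats <- function(motifs, fractions = FALSE,
                                   max_nonpositive = 0.05) {
  pairs <- if (inherits(motifs, "ei_motifs")) motifs$pairs else motifs
  stopifnot(nrow(pairs) >= 3)
  orders <- grep("^R[0-9]+$", names(pairs), value = TRUE)
  r2 <- function(y, x) {
    f <- lm(y ~ x)
    summary(f)$r.squared
  }
  ord_tbl <- purrr::map_dfr(orders, function(o) {
    tibble::tibble(term = o, order = as.integer(sub("R", "", o)),
                   r_squared = r2(pairs$total, pairs[[o]]))
  })
  if (fractions) {
    npos <- mean(pairs$total <= 0)
    if (npos > max_nonpositive)
      stop(sprintf(paste0(
        "%.1f%% of pairs have nonpositive total correlation; the ",
        "fraction-of-total measure cannot be used in this regime"),
        100 * npos))
    keep <- pairs$total > 0
    if (any(!keep))
      message("dropping ", sum(!keep),
              " pair(s) with nonpositive total correlation")
    ord_tbl$fraction <- vapply(orders, function(o) {
      mean(pairs[[o]][keep] / pairs$total[keep])
    }, numeric(1))
  }
  mt <- intersect(c("chain_E", "chain_I", "common_E", "common_I"),
                  names(pairs))
  if ("R2" %in% names(pairs) && length(mt) == 4) {
    mt_tbl <- purrr::map_dfr(mt, function(m) {
      tibble::tibble(term = m, order = 2L,
                     r_squared = r2(pairs$R2, pairs[[m]]))
    })
    ord_tbl <- dplyr::bind_rows(ord_tbl, mt_tbl)
  }
  ord_tbl
}

#' Second-order contributions split by motif type
#'
#' Convenience accessor for the four normalized second-order motif
#' matrices; their sum equals the order-2 contribution entrywise.
#'
#' @param motifs an [motif_decomposition()].
#' @return Named list of matrices `chain_E`, `chain_I`, `common_E`,
#'   `common_I`.
#' @export
second_order_by_motif <- function(motifs) {
  stopifnot(inherits(motifs, "ei_motifs"))
  motifs$by_type
}
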