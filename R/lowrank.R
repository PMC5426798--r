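#' Optimal identity shift for a rank-one approximation
#'
#' Given the (descending) eigenvalues of a symmetric PSD correlation
#' matrix, returns the shift `lambda` that maximizes the fraction of the
#' squared Frobenius norm of `C - lambda I` captured by the leading
#' singular direction:
#' `lambda = lambda_1 - sum_{j>1}(lambda_1-lambda_j)^2 /
#' sum_{j>1}(lambda_1-lambda_j)`.
#'
#' @param eigenvalues numeric vector, sorted in decreasing order.
#' @return The scalar shift `lambda`.
#' @examples
#' lambda_shift(c(5, 1, 1, 1)) # exact diag + rank-one: returns 1
#' @export
lambda_shift <- function(eigenvalues) {
  stopifnot(length(eigenvalues) >= 2,
            !is.unsorted(rev(eigenvalues), strictly = FALSE))
  l1 <- eigenvalues[1]
  d <- l1 - eigenvalues[-1]
  if (sum(d) <= 0)
    stop("all eigenvalues are equal; the shift is undefined")
  l1 - sum(d^2) / sum(d)
}

#' Shifted rank-one approximation of a correlation matrix
#'
#' Approximates a symmetric correlation matrix as
#' `C ~ lambda I + (sigma_1 - lambda) u_1 u_1^T`, with `lambda` chosen in
#' closed form ([lambda_shift()]) to maximize the Frobenius fraction of
#' `C - lambda I` captured by the leading eigendirection.  For a
#' correlation matrix whose off-diagonal follows `rho_ij =
#' c S(nu_i) S(nu_j)`, the weights `u_1` recover the rate-dependent gain
#' profile `S(nu)`.
#'
#' @param C symmetric PSD matrix (unit diagonal for a correlation
#'   matrix).
#' @param rates optional per-cell rates used to orient `u_1` (so its
#'   rate-weighted mean entry is nonnegative); plain mean if omitted.
#' @param rank_tol relative tolerance below which trailing eigenvalues
#'   are treated as zero when counting the rank.
#' @return Object of class `ei_lowrank`: `lambda`, `sigma1`, `u1`,
#'   `approx` (`lambda I + (sigma1-lambda) u1 u1^T`), `residual` matrix,
#'   `frobenius_fraction`, `eigenvalues`, `rank`.
#' @export
rank_one_approx <- function(C, rates = NULL, rank_tol = 1e-12) {
  if (!isSymmetric(unname(C), tol = 1e-8))
    stop("C must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ev <- e$values
  r <- sum(ev > rank_tol * max(abs(ev)))
  lambda <- lambda_shift(ev)
  sigma1 <- ev[1]
  u1 <- e$vectors[, 1]
  wts <- if (is.null(rates)) rep(1, length(u1)) else rates
  if (sum(u1 * wts) < 0) u1 <- -u1
  approx <- lambda * diag(nrow(C)) + (sigma1 - lambda) * tcrossprod(u1)
  resid <- C - approx
  fr <- (sigma1 - lambda)^2 / sum((ev - lambda)^2)
  structure(list(lambda = lambda, sigma1 = sigma1, u1 = u1,
                 approx = approx, residual = resid,
                 frobenius_fraction = fr, eigenvalues = ev, rank = r,
                 rates = rates),
            class = "ei_lowrank")
}

#' @export
print.ei_lowrank <- function(x, ...) {
  cat(sprintf(
    "<ei_lowrank> lambda = %.4f, sigma1 = %.4f, Frobenius fraction %.3f\n",
    x$lambda, x$sigma1, x$frobenius_fraction))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ei_lowrank <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma1 = x$sigma1,
                 frobenius_fraction = x$frobenius_fraction,
                 rank = x$rank)
}

#' @exportS3Method generics::tidy
tidy.ei_lowrank <- function(x, ...) {
  out <- tibble::tibble(cell = seq_along(x$u1), u1 = x$u1)
  if (!is.null(x$rates)) out$rate_hz <- x$rates
  out
}

#' Diagnostics of the rank-one approximation
#'
#' Off-diagonal scatter of approximated vs true correlations (range,
#' OLS R^2) and the association between the leading-vector weights and
#' firing rate (Spearman rank correlation and OLS R^2): when correlation
#' increases with rate, the approximation tracks the truth and `u_1`
#' aligns with the rate profile.
#'
#' @param C the original correlation matrix.
#' @param result an [rank_one_approx()] of `C`.
#' @param rates per-cell firing rates (Hz).
#' @return Tibble with one row of diagnostics.
#' @export
approximation_quality <- function(C, result, rates) {
  stopifnot(inherits(result, "ei_lowrank"),
            length(rates) == nrow(C))
  off <- upper.tri(C)
  tru <- C[off]; app <- result$approx[off]
  fit <- lm(tru ~ app)
  ufit <- lm(result$u1 ~ rates)
  tibble::tibble(
    approx_min = min(app), approx_max = max(app),
    true_min = min(tru), true_max = max(tru),
    r_squared_offdiag = summary(fit)$r.squared,
    u1_rate_spearman = suppressWarnings(
      cor(result$u1, rates, method = "spearman")),
    u1_rate_r_squared = summary(ufit)$r.squared,
    frobenius_fraction = result$frobenius_fraction
  )
}

#' E-E correlation matrix ordered by firing rate
#'
#' Extracts the excitatory block of a correlation matrix (from
#' [spike_count_stats()] or [lr_correlations()]) with unit diagonal,
#' ordered by decreasing firing rate.
#'
#' @param rho full correlation matrix.
#' @param cells tibble with `type` and `rate_hz` aligned with `rho`.
#' @return The reordered E-E correlation matrix with the ordering rates
#'   in attribute `"rates"`.
#' @export
ee_correlation_matrix <- function(rho, cells) {
  sel <- which(cells$type == "E")
  ord <- sel[order(cells$rate_hz[sel], decreasing = TRUE)]
  out <- rho[ord, ord]
  diag(out) <- 1
  attr(out, "rates") <- cells$rate_hz[ord]
  attr(out, "cells") <- cells$id[ord]
  out
}
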