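#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_line
#'   geom_abline facet_wrap labs scale_color_viridis_d scale_fill_viridis_c
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot spike-count correlations against geometric-mean rate
#'
#' @param object an `ei_count_stats` from [spike_count_stats()].
#' @param pair_types restrict to pairs of these types (default E-E).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ei_count_stats <- function(object, pair_types = c("E", "E"),
                                    ...) {
  p <- dplyr::filter(object$pairs, .data$type_i == pair_types[1],
                     .data$type_j == pair_types[2])
  ggplot(p, aes(x = .data$geom_rate, y = .data$rho)) +
    geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    labs(x = expression(sqrt(nu[i] * nu[j]) ~ "(Hz)"),
         y = expression(rho[ij]),
         title = sprintf("Spike-count correlation, T = %g ms", object$T)) +
    theme_minimal()
}

#' Plot linear-response correlations per window
#'
#' @param object an `ei_lr_correlations` from [lr_correlations()].
#' @param ... unused.
#' @return A ggplot faceted by window.
#' @export
autoplot.ei_lr_correlations <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::filter(long, .data$type_i == "E", .data$type_j == "E")
  ggplot(long, aes(x = .data$geom_rate, y = .data$rho)) +
    geom_point(alpha = 0.4, size = 0.8, colour = "magenta4") +
    facet_wrap(~window, scales = "free_y",
               labeller = ggplot2::label_both) +
    labs(x = expression(sqrt(nu[i] * nu[j]) ~ "(Hz)"),
         y = expression(rho[ij]),
         title = "Linear-response predicted correlations") +
    theme_minimal()
}

#' Plot motif contributions against rate or total correlation
#'
#' @param object an `ei_motifs` from [motif_decomposition()].
#' @param x_var `"geom_rate"` or `"total"`.
#' @param ... unused.
#' @return A ggplot coloured by path order.
#' @export
autoplot.ei_motifs <- function(object, x_var = c("geom_rate", "total"),
                               ...) {
  x_var <- match.arg(x_var)
  long <- tidyr::pivot_longer(object$pairs,
                              dplyr::matches("^R[0-9]+$"),
                              names_to = "order", values_to = "value")
  ggplot(long, aes(x = .data[[x_var]], y = .data$value,
                   colour = .data$order)) +
    geom_point(alpha = 0.3, size = 0.6) +
    scale_color_viridis_d() +
    labs(x = if (x_var == "geom_rate")
               expression(sqrt(nu[i] * nu[j]) ~ "(Hz)")
             else "total normalized correlation",
         y = expression(tilde(R)[ij]^k),
         title = "Path-order contributions to correlation") +
    theme_minimal()
}

#' Plot the rate / susceptibility surface
#'
#' @param object an `ei_rate_surface`.
#' @param fill `"susceptibility"` or `"rate_hz"`.
#' @param ... unused.
#' @return A ggplot with the network's cells and the theta = 1 path
#'   overlaid.
#' @export
autoplot.ei_rate_surface <- function(object,
                                     fill = c("susceptibility", "rate_hz"),
                                     ...) {
  fill <- match.arg(fill)
  ggplot(object$grid, aes(x = .data$gI_mean, y = .data$theta)) +
    geom_tile(aes(fill = .data[[fill]])) +
    scale_fill_viridis_c() +
    geom_point(data = object$cells, colour = "red", size = 0.8) +
    geom_line(data = object$theta1_path, colour = "black",
              linetype = 2) +
    labs(x = expression(group(langle, g[I], rangle)),
         y = expression(theta), fill = fill,
         title = "Reduced rate function landscape") +
    theme_minimal()
}

#' Plot rank-one approximated vs true correlations
#'
#' @param object an `ei_lowrank`.
#' @param C the original correlation matrix the approximation was fit to.
#' @param ... unused.
#' @return A ggplot of off-diagonal entries with the unity line.
#' @export
autoplot.ei_lowrank <- function(object, C, ...) {
  off <- upper.tri(C)
  d <- tibble::tibble(true = C[off], approx = object$approx[off])
  ggplot(d, aes(x = .data$approx, y = .data$true)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    labs(x = "rank-one approximation", y = "measured correlation",
         title = sprintf("Shifted rank-one fit (Frobenius fraction %.2f)",
                         object$frobenius_fraction)) +
    theme_minimal()
}
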