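#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an allele-frequency trajectory
#'
#' Allele frequency and observed heterozygosity against generation for one
#' replicate, drifting from near `p0` to an absorbing boundary.
#'
#' @param object A `drift_trajectory` run with `record = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drift_trajectory <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("f_A", "H_obs"), names_to = "statistic")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$value,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(f_A = "#1b6ca8", H_obs = "#c2571a"),
      labels = c(f_A = "allele frequency f(A)",
                 H_obs = "observed heterozygosity")) +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fixation-time distribution with its inverse-Gaussian fit
#'
#' @param object A `fixation_sample` from [run_replicates()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fixation_sample <- function(object, bins = 40, ...) {
  x <- object$t_h[!object$capped]
  fit <- fit_inverse_gaussian(x)
  grid <- seq(min(x), max(x), length.out = 256)
  dens <- tibble::tibble(t_h = grid,
                         density = exp(dinvgauss_log(grid, fit$mu, fit$lambda)))
  ggplot2::ggplot(tibble::tibble(t_h = x), ggplot2::aes(.data$t_h)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$density),
                       colour = "#1b6ca8", linewidth = 0.8) +
    ggplot2::labs(x = "fixation time T_h (generations)", y = "density",
                  subtitle = sprintf("inverse-Gaussian MLE: mu = %.1f, lambda = %.1f",
                                     fit$mu, fit$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot mean fixation time against population size
#'
#' One point per sweep cell with the through-origin proportionality line per
#' topology.
#'
#' @param object A `sweep_result` from [sweep_sizes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  cells <- object$cells
  lines <- object$slopes |>
    dplyr::mutate(size = list(c(0, max(cells$size)))) |>
    tidyr::unnest("size") |>
    dplyr::mutate(t_ave = .data$slope * .data$size)
  ggplot2::ggplot(cells, ggplot2::aes(.data$size, .data$t_ave,
                                      colour = .data$topology)) +
    ggplot2::geom_line(data = lines, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$t_ave - 2 * .data$se,
                                          ymax = .data$t_ave + 2 * .data$se)) +
    ggplot2::labs(x = "population size N", y = "mean fixation time T_ave",
                  colour = "topology") +
    ggplot2::theme_minimal()
}

#' Plot a genotype map with cluster boundaries
#'
#' Tile map of the lattice: homozygous AA / aa patches and boundary
#' heterozygotes.
#'
#' @param object A `population_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.population_grid <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object))) |>
    dplyr::mutate(genotype = factor(
      c("aa", "Aa", "AA")[unclass(object)[cbind(.data$row, .data$col)] + 1L],
      levels = c("AA", "Aa", "aa")))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$genotype)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(AA = "#1b6ca8", Aa = "#f2e86d",
                                          aa = "#c2571a")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean heterozygosity curves
#'
#' @param curves Output of [heterozygosity_curves()].
#' @return A ggplot.
#' @export
plot_heterozygosity_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$generation, .data$mean_H,
                                       colour = .data$topology)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_H - 2 * .data$se,
                                      ymax = .data$mean_H + 2 * .data$se,
                                      fill = .data$topology),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "mean observed heterozygosity") +
    ggplot2::theme_minimal()
}
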