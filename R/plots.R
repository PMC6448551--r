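#' Manhattan-style plot of per-SNP ROH incidence
#'
#' @param track A [snp_roh_incidence()] track.
#' @param threshold Optional horizontal reference line (e.g. the realized
#'   island threshold).
#' @return A ggplot.
#' @export
plot_incidence <- function(track, threshold = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos_bp / 1e6,
                                           y = .data$proportion)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Proportion of individuals in ROH")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Genome-wide |iHS| plot
#'
#' @param ihs An [ihs_scan()] result.
#' @param threshold |iHS| significance line (default 2.81, the two-sided
#'   p = 0.005 cutoff).
#' @return A ggplot.
#' @export
plot_ihs <- function(ihs, threshold = significance_threshold(0.005)) {
  ggplot2::ggplot(dplyr::filter(tibble::as_tibble(ihs), !is.na(.data$ihs_std)),
                  ggplot2::aes(x = .data$pos_bp / 1e6, y = abs(.data$ihs_std))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "|iHS|")
}

#' LD decay plot from binned pairs
#'
#' @param bins A [bin_ld()] table.
#' @return A ggplot of mean r² (raw and adjusted) against distance.
#' @export
plot_ld_decay <- function(bins) {
  long <- tibble::as_tibble(bins) |>
    dplyr::filter(.data$n_pairs > 0) |>
    tidyr::pivot_longer(c("mean_r2", "mean_r2adj"), names_to = "measure",
                        values_to = "r2")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dist_mid / 1e6, y = .data$r2,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Distance (Mb)", y = expression(mean ~ r^2),
                  colour = NULL)
}

#' Effective-population-size trajectory plot
#'
#' @param ne A [ne_trajectory()] table.
#' @return A ggplot of Ne against generations ago (log-log).
#' @export
plot_ne <- function(ne) {
  ggplot2::ggplot(dplyr::filter(tibble::as_tibble(ne), .data$flag == "ok"),
                  ggplot2::aes(x = .data$t, y = .data$ne)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Generations ago", y = expression(N[e]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.roh_incidence <- function(object, ...) plot_incidence(object, ...)

#' @export
autoplot.ihs_result <- function(object, ...) plot_ihs(object, ...)

#' @export
autoplot.ld_bins <- function(object, ...) plot_ld_decay(object)

#' @export
autoplot.ne_trajectory <- function(object, ...) plot_ne(object)
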