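# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_hline labs coord_cartesian scale_x_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a DLVO interaction-energy profile
#'
#' Total, van der Waals and double-layer energies (in k_B T) against
#' separation.
#'
#' @param object An `nf_dlvo_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot nf_dlvo_profile
#' @export
autoplot.nf_dlvo_profile <- function(object, ...) {
  p <- attr(object, "params")
  kT <- .nf_const$k_B * p$temperature_K
  long <- tidyr::pivot_longer(
    dplyr::transmute(as_tibble(object), D_nm = .data$D_nm,
                     total = .data$v_total_kBT,
                     `van der Waals` = .data$v_vdw_J / kT,
                     `double layer` = .data$v_edl_J / kT),
    -"D_nm", names_to = "term", values_to = "v_kBT")
  ggplot(long, aes(x = .data$D_nm, y = .data$v_kBT, colour = .data$term)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    coord_cartesian(ylim = range(object$v_total_kBT) + c(-1, 1)) +
    labs(x = "separation D (nm)", y = expression(V / k[B] * T),
         colour = NULL,
         title = sprintf("DLVO profile: zeta = %.1f mV, I = %.3g M",
                         p$zeta_mV, p$ionic_strength_M))
}

#' Plot a per-component percent distribution
#'
#' Ranked bar chart of a component's species percentages, e.g. the
#' dissolved-silver distribution from [speciate_dissolved_silver()].
#'
#' @param distribution A tibble with `species` and `percent` columns.
#' @param min_percent Hide species below this share (default 0.5).
#' @return A ggplot.
#' @export
plot_distribution <- function(distribution, min_percent = 0.5) {
  d <- dplyr::filter(as_tibble(distribution), .data$percent >= min_percent)
  d$species <- factor(d$species, levels = rev(d$species))
  ggplot(d, aes(x = .data$percent, y = .data$species)) +
    geom_col(fill = "steelblue") +
    labs(x = "% of component total", y = NULL)
}

#' Plot an aggregation-rate analysis
#'
#' Size series with the detected plateau and the interval rates.
#'
#' @param object An `nf_rates`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot nf_rates
#' @export
autoplot.nf_rates <- function(object, ...) {
  s <- object$summary
  p <- ggplot(object$series, aes(x = .data$time_min, y = .data$size_nm)) +
    geom_point() + geom_line(alpha = 0.4) +
    labs(x = "time (min)", y = "hydrodynamic size (nm)")
  if (!is.na(s$plateau_size_nm)) {
    p <- p + geom_hline(yintercept = s$plateau_size_nm,
                        linetype = 2, colour = "firebrick")
  }
  p
}
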