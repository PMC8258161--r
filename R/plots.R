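#' Scatter plot of the aggregated design metrics
#'
#' One point per (mixture, n_act): median D-criterion against coverage,
#' colored by tracer cost and faceted by the number of active fluxes — the
#' standard exploration view for trading off information, robustness and
#' price.
#'
#' @param object a `red_aggregated` from [aggregate_pool()].
#' @param n_act optional subset of design sizes to show.
#' @param coverage_line horizontal guide (percent), e.g. a 95% cut-off.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot red_aggregated
#' @export
autoplot.red_aggregated <- function(object, n_act = NULL, coverage_line = 95,
                                    ...) {
  df <- object$metrics
  if (!is.null(n_act)) df <- df[df$n_act %in% n_act, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi_d_med, y = .data$coverage,
                                   color = .data$cost)) +
    ggplot2::geom_hline(yintercept = coverage_line, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~n_act, labeller = ggplot2::label_both) +
    ggplot2::scale_color_viridis_c(name = "cost [$]") +
    ggplot2::labs(x = expression(hat(Phi)[D]), y = "coverage [%]") +
    ggplot2::theme_bw()
}

#' Ternary mixture-triangle plot
#'
#' Projects a three-species [ternary_slice()] onto triangle coordinates and
#' colors the points by a chosen metric; gray points mark mixtures where the
#' metric is undefined (singular designs).
#'
#' @param slice tibble from [ternary_slice()]; the first three non-`mixture`
#'   columns are taken as the species fractions.
#' @param metric column to color by (`"phi_d_med"`, `"coverage"`, `"cost"`).
#' @return a ggplot object.
#' @export
plot_ternary <- function(slice, metric = "phi_d_med") {
  sp <- setdiff(names(slice), c("mixture", "phi_d_med", "coverage", "cost"))[1:3]
  df <- slice
  df$.x <- df[[sp[2]]] + df[[sp[3]]] / 2
  df$.y <- df[[sp[3]]] * sqrt(3) / 2
  corners <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.x, y = .data$.y)) +
    ggplot2::geom_path(data = corners, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data[[metric]]), size = 3) +
    ggplot2::scale_color_viridis_c(na.value = "grey70") +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.05),
                      label = sp) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Per-flux identifiability summary plot
#'
#' Bars: relative frequency with which each flux is identifiable; points and
#' ranges: quartiles of the flux standard deviation when identified.
#'
#' @param flux_stats tibble from [aggregate_pool()]'s `flux_stats` or
#'   [partial_design()] (with a `flux` column added).
#' @return a ggplot object.
#' @export
plot_flux_identifiability <- function(flux_stats) {
  ggplot2::ggplot(flux_stats, ggplot2::aes(x = factor(.data$mixture))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$ident_freq), fill = "firebrick",
                      alpha = 0.6, width = 0.5) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$sd_med / max(c(.data$sd_q3, 1), na.rm = TRUE),
                                          ymin = .data$sd_q1 / max(c(.data$sd_q3, 1), na.rm = TRUE),
                                          ymax = .data$sd_q3 / max(c(.data$sd_q3, 1), na.rm = TRUE)),
                             na.rm = TRUE) +
    ggplot2::facet_wrap(~flux) +
    ggplot2::labs(x = "mixture", y = "identifiability frequency / scaled sd") +
    ggplot2::theme_bw()
}
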