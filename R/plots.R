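#' Tornado diagram
#'
#' Horizontal bars spanning the ICER obtained at each parameter's low
#' and high bound, widest at the top.
#'
#' @param tornado A `tornado` tibble from [one_way()].
#' @param top Number of parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 12) {
  df <- utils::head(tornado, top)
  df$param <- factor(df$param, levels = rev(df$param))
  base_icer <- attr(tornado, "base_icer")
  ggplot2::ggplot(df, ggplot2::aes(y = param)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_at_low,
                                       xend = icer_at_high,
                                       yend = param),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_points Tibble from [ceac()].
#' @param wtp Optional reference threshold drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_points, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_points,
                       ggplot2::aes(wtp,
                                    prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp,
                                                  linetype = 2)
  p
}

#' Cost-effectiveness plane scatter
#'
#' @param draws A `psa_draws` tibble from [run_psa()].
#' @param wtp Threshold for the reference line and point colouring.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, wtp = attr(draws, "wtp")) {
  df <- ce_plane(draws, wtp)
  ggplot2::ggplot(df, ggplot2::aes(incr_qaly, incr_cost,
                                   colour = cost_effective)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey40"),
                                 name = "NMB > 0") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
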