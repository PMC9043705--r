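#' Histograms of heading biases by probe distance
#'
#' One panel per probe distance; 0 marks the probe target and the dashed
#' line the frequent-target location, so planning biases appear as mass near
#' the dashed line and execution biases as a small rightward shift of the
#' peak at 0.
#'
#' @param observations observation tibble; valid test-phase probe trials are
#'   plotted.
#' @param binwidth histogram bin width in degrees.
#' @return a ggplot object.
#' @export
plot_heading_distribution <- function(observations, binwidth = 5) {
  obs <- dplyr::filter(observations, .data$valid, .data$is_probe,
                       .data$phase == "test")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$bias_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$probe_distance),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::facet_wrap(~probe_distance, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "heading bias toward frequent target (deg)",
                  y = "trials") +
    ggplot2::theme_minimal()
}

#' Group quintile curves of bias versus RT
#'
#' @param quintiles an `udl_quintiles` object from [quintile_summary()].
#' @return a ggplot object.
#' @export
plot_quintiles <- function(quintiles) {
  grp <- quintiles$group
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$mean_rt_s, y = .data$bias_deg,
                                    colour = factor(.data$probe_distance))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$bias_deg - .data$sem_deg,
      ymax = .data$bias_deg + .data$sem_deg)) +
    ggplot2::labs(x = "mean RT (s)", y = "mean bias (deg)",
                  colour = "probe distance (deg)") +
    ggplot2::theme_minimal()
}
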