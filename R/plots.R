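#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filtered record
#'
#' Measurement, posterior mean and a +/- 2 sd posterior band per lead.
#'
#' @param object A [gp_filter()] result.
#' @param window Optional two-element time window in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_filter_result <- function(object, window = NULL, ...) {
  df <- tidy(object)
  if (!is.null(window))
    df <- dplyr::filter(df, .data$time_s >= window[1], .data$time_s <= window[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$measurement),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$posterior - 2 * sqrt(.data$post_var),
                                      ymax = .data$posterior + 2 * sqrt(.data$post_var)),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$posterior), colour = "steelblue") +
    ggplot2::facet_wrap(~lead, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = "GP posterior-mean filter (band: +/- 2 sd)")
}

#' Plot SNR improvement across the benchmark grid
#'
#' Mean +/- one standard deviation of the improvement per input SNR level
#' and method.
#'
#' @param bench A [run_benchmark_grid()] result.
#' @return A ggplot object.
#' @export
plot_snr_improvement <- function(bench) {
  s <- summarise_snr(bench)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$input_snr_db, y = .data$mean_db,
                                  colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_db - .data$sd_db,
                                          ymax = .data$mean_db + .data$sd_db),
                             position = ggplot2::position_dodge(width = 1.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 1.2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "input SNR (dB)", y = "SNR improvement (dB)",
                  title = "Mean +/- sd SNR improvement")
}

#' Plot QT estimation error across the benchmark grid
#'
#' Median and interquartile range of the per-cell median QT error.
#'
#' @param bench A [run_benchmark_grid()] result with QT rows.
#' @return A ggplot object.
#' @export
plot_delta_qt <- function(bench) {
  s <- summarise_qt(bench)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$input_snr_db,
                                  y = 1000 * .data$median_dqt_s,
                                  colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = 1000 * (.data$median_dqt_s - .data$iqr_dqt_s / 2),
      ymax = 1000 * (.data$median_dqt_s + .data$iqr_dqt_s / 2)),
      position = ggplot2::position_dodge(width = 1.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 1.2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "input SNR (dB)", y = "QT error (ms)",
                  title = "Median (+/- IQR/2) QT estimation error")
}

#' @export
autoplot.gp_benchmark <- function(object, ...) plot_snr_improvement(object)
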