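#' Plot an inflow curve
#'
#' Line plot of the inflow curve over the cardiac cycle; if a `peak_pair` is
#' supplied, the detected E and A peaks and the diastolic window are marked.
#'
#' @param object An [inflow_curve()].
#' @param peaks Optional `peak_pair` from [detect_ea_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inflow_curve <- function(object, peaks = NULL, ...) {
  df <- as_tibble.inflow_curve(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ms)",
                  y = sprintf("%s (%s)", object$kind, curve_units(object$kind))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::annotate("rect",
                               xmin = peaks$diastole_window[1],
                               xmax = peaks$diastole_window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
    if (!peaks$fused) {
      pk <- tibble(time_ms = c(peaks$e_time, peaks$a_time),
                   value = c(peaks$e_value, peaks$a_value),
                   label = c("E", "A"))
      p <- p +
        ggplot2::geom_point(data = pk, colour = "red", size = 2) +
        ggplot2::geom_text(data = pk, ggplot2::aes(label = .data$label),
                           vjust = -1, colour = "red")
    }
  }
  p
}

#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means with the mean
#' difference and the mean ± 2 SD limits of agreement.
#'
#' @param ba A [bland_altman()] result.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, xlab = "pair mean", ylab = "difference") {
  df <- tibble(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Regression panel for an agreement report
#'
#' One facet per metric, plotting method against reference values is not
#' possible from the aggregated report alone, so this shows the fitted
#' coefficients: R^2 per method pair and metric.
#'
#' @param object An `agreement_report` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- as_tibble(object)
  df$pair <- paste(df$method, "vs", df$reference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$r_squared,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
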