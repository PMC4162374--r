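#' Raster plot of spike data
#'
#' @param object A `spike_data` tibble.
#' @param ... Unused.
#' @return A ggplot object (time on x, neuron index on y, coloured by
#'   population).
#' @export
autoplot.spike_data <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$neuron,
                                       colour = .data$population)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(E = "#c0392b", I = "#2c5aa0")) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean-field f-I curves
#'
#' @param object A `rate_curve` tibble from [fI_curve()].
#' @param ... Unused.
#' @return A ggplot object with one line per population.
#' @export
autoplot.rate_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("nu_E", "nu_I"), names_to = "population",
                              names_prefix = "nu_", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$rate,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(E = "#c0392b", I = "#2c5aa0")) +
    ggplot2::labs(x = expression(mu ~ "(mV)"), y = "rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a heterogeneity phase diagram
#'
#' @param object A `phase_diagram` tibble.
#' @param ... Unused.
#' @return A ggplot tile plot of the asynchronous/synchronous regimes.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$w_E, y = .data$w_I,
                                       fill = .data$regime)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(asynchronous = "#78b4e0",
                                          synchronous = "#e0a078")) +
    ggplot2::labs(x = expression(w[E] ~ "(mV)"), y = expression(w[I] ~ "(mV)"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a covariance sweep
#'
#' @param object A `covariance_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot of covariance (with standard-error bars) vs
#'   heterogeneity width.
#' @export
autoplot.covariance_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$w, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$C - .data$se,
                                          ymax = .data$C + .data$se)) +
    ggplot2::labs(x = sprintf("w_%s (mV)", attr(object, "axis")),
                  y = "input-output covariance (mV Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a divisive-gain fit
#'
#' Overlays the target f-I curve and the optimally rescaled reference
#' curve, the visual check that the heterogeneity effect is divisive.
#'
#' @param x A `gain_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_gain_fit <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rw, colour = "target")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rescaled,
                                     colour = "rescaled reference")) +
    ggplot2::scale_colour_manual(values = c(target = "#2c5aa0",
                                            `rescaled reference` = "#c0392b")) +
    ggplot2::labs(x = expression(mu ~ "(mV)"), y = "excitatory rate (Hz)",
                  colour = NULL,
                  subtitle = sprintf("zeta = %.3f, Delta = %.4g", x$zeta,
                                     x$delta)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
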