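#' Nyquist plot of an impedance spectrum
#'
#' `-Im(Z)` against `Re(Z)`, with an optional fitted-model overlay on a
#' denser grid. Axes share a common scale so a charge-transfer semicircle
#' looks like one.
#'
#' @param spectrum A spectrum data frame.
#' @param params Optional [randles_params()] row for the model curve.
#' @return A ggplot object.
#' @export
plot_nyquist <- function(spectrum, params = NULL) {
  d <- export_plots_data(spectrum, params)$nyquist
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$z_real_ohm, y = .data$neg_z_imag_ohm)
  ) +
    ggplot2::geom_path(
      data = ~ dplyr::filter(.x, .data$source == "model"),
      color = "grey40"
    ) +
    ggplot2::geom_point(
      data = ~ dplyr::filter(.x, .data$source == "data"),
      color = "#2166ac", size = 1.4
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(Z[real] ~ (Omega)), y = expression(-Z[imag] ~ (Omega)),
      title = spectrum_label(spectrum)
    ) +
    ggplot2::theme_minimal()
  p
}

#' Bode plot of an impedance spectrum
#'
#' Impedance magnitude (log-log) and phase (degrees, log-x) against
#' frequency, faceted, with an optional model overlay.
#'
#' @inheritParams plot_nyquist
#' @return A ggplot object.
#' @export
plot_bode <- function(spectrum, params = NULL) {
  d <- export_plots_data(spectrum, params)$bode |>
    tidyr::pivot_longer(c("magnitude_ohm", "phase_deg"),
                        names_to = "panel", values_to = "value") |>
    dplyr::mutate(panel = dplyr::recode(.data$panel,
                                        magnitude_ohm = "|Z| (ohm)",
                                        phase_deg = "phase (deg)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency_hz, y = .data$value)) +
    ggplot2::geom_path(
      data = ~ dplyr::filter(.x, .data$source == "model"), color = "grey40"
    ) +
    ggplot2::geom_point(
      data = ~ dplyr::filter(.x, .data$source == "data"),
      color = "#2166ac", size = 1.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = spectrum_label(spectrum)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_nyquist
#' @param object A `randles_fit` object.
#' @param ... Unused.
#' @export
autoplot.randles_fit <- function(object, ...) {
  plot_nyquist(object$data, object$params) +
    ggplot2::labs(subtitle = sprintf(
      "r_u = %.4g, r_p = %.4g ohm, alpha = %.3f (%s)",
      object$params$r_u, object$params$r_p, object$params$alpha,
      if (object$converged) "converged" else "not converged"
    ))
}

#' DEP response plot
#'
#' `Re(f_CM)` against frequency with crossovers marked and the recommended
#' positive-DEP operating band shaded.
#'
#' @param object A `dep_prediction` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dep_prediction <- function(object, ...) {
  p <- ggplot2::ggplot(object$spectrum,
                       ggplot2::aes(x = .data$frequency_hz, y = .data$re_fcm))
  if (!is.null(object$recommended_band)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = object$recommended_band[1],
      xmax = object$recommended_band[2], ymin = -Inf, ymax = Inf,
      fill = "#74c476", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$crossover_hz,
                        linetype = 3, color = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(Re ~ f[CM])) +
    ggplot2::theme_minimal()
}

#' Permittivity spectrum plot
#'
#' Relative permittivity components and conductivity against frequency.
#'
#' @param object A `permittivity_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permittivity_spectrum <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("eps_real", "eps_imag", "sigma_s_per_m"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency_hz, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
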