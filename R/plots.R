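## ggplot2 views of each result type.

#' @rdname fit_hyperbolic
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
                         length.out = 200))
  grid$y <- predict(object, newdata = grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "titrant (µM)", y = "observable",
                  title = sprintf("Hyperbolic fit: Kd = %.3g µM, R² = %.3f",
                                  object$kd, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname analyze_thermogram
#' @param object An `unfolding_fit` (for `autoplot`).
#' @method autoplot unfolding_fit
#' @export
autoplot.unfolding_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$temperature, y = .data$cp)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tm, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "temperature (°C)",
                  y = expression(C[p] ~ "(kJ" ~ mol^-1 ~ K^-1 * ")"),
                  title = sprintf("Tm = %.2f °C, ΔH(cal) = %.0f kJ/mol",
                                  object$tm, object$dh_cal)) +
    ggplot2::theme_minimal()
  if (!is.na(object$dh_vh)) {
    fitted <- dplyr::mutate(object$data,
                            cp = two_state_cp(.data$temperature, object$tm,
                                              object$dh_vh))
    p <- p + ggplot2::geom_line(data = fitted, colour = "steelblue",
                                linetype = "dotted")
  }
  p
}

#' Plot a hydropathy profile with called segments
#'
#' @param profile A tibble from [hydropathy_profile()].
#' @param segments Optional segment table from [call_segments()], drawn as
#'   shaded spans.
#' @param threshold Favorability threshold line (default 0).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, segments = NULL, threshold = 0) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$center, y = .data$dg)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue (window centre)",
                  y = expression(Delta * G ~ "(kcal/mol, water" %->%
                                   "interface)")) +
    ggplot2::facet_wrap(~sequence_id) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Plot one or more far-UV CD spectra
#'
#' @param spectra A spectrum tibble, optionally with a `label` column to
#'   colour multiple spectra.
#' @return A ggplot object.
#' @export
plot_cd_spectra <- function(spectra) {
  aes <- if ("label" %in% names(spectra)) {
    ggplot2::aes(x = .data$wavelength, y = .data$ellipticity,
                 colour = .data$label)
  } else {
    ggplot2::aes(x = .data$wavelength, y = .data$ellipticity)
  }
  ggplot2::ggplot(spectra, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression("[" * theta * "] (deg" ~ cm^2 ~
                                   dmol^-1 * ")")) +
    ggplot2::theme_minimal()
}
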