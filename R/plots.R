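#' Plot a spectrum as a stick plot
#'
#' @param object A spectrum.
#' @param log_y Plot intensities on a log10 axis (default TRUE; spectra
#'   span orders of magnitude).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$mz, xend = .data$mz,
                                    y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(linewidth = 0.2) +
    ggplot2::labs(
      x = "m/z (Th)",
      y = if (spectrum_scale(object) == "standardized")
        "standardized intensity" else "intensity (a.u.)",
      title = spectrum_label(object)
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a normalization curve over its knee points
#'
#' @param object A `normalization_curve`.
#' @param ... Unused.
#' @return A ggplot showing the knee points and the smoothing spline.
#' @export
autoplot.normalization_curve <- function(object, ...) {
  grid <- tibble::tibble(center_mz = seq(object$range[1], object$range[2],
                                         length.out = 512))
  grid$value <- predict(object, grid$center_mz)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$center_mz, y = .data$value)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "window center m/z (Th)", y = "knee value (a.u.)",
                  title = "Normalization curve")
}

#' Scatter plot of matched standardized intensities
#'
#' @param object A `spectra_concordance`.
#' @param log_axes Use log10 axes (default TRUE).
#' @param ... Unused.
#' @return A ggplot with the identity line, OLS fit and Passing-Bablok fit.
#' @export
autoplot.spectra_concordance <- function(object, log_axes = TRUE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object$pairs),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$linear$slope,
                         intercept = object$linear$intercept, colour = "blue") +
    ggplot2::geom_abline(slope = object$pb$pb_slope,
                         intercept = object$pb$pb_intercept, colour = "red") +
    ggplot2::labs(x = object$labels[1], y = object$labels[2],
                  title = sprintf("R^2 = %.3f, slope = %.3f", object$linear$r2,
                                  object$linear$slope))
  if (log_axes) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a window's ranked intensities with its power fit and knee
#'
#' The diagnostic view behind the algorithm: descending window
#' intensities, the fitted `y = a*x^b + c` curve, and the knee point used
#' as the window's normalization value.
#'
#' @param spectrum A spectrum or peak data frame.
#' @param center_mz Window center (Thomson).
#' @param width Window width (default 50).
#' @param min_peaks Minimum occupancy (default 20).
#' @return A ggplot.
#' @export
plot_ranked_window <- function(spectrum, center_mz, width = 50, min_peaks = 20) {
  s <- as_spectrum(spectrum)
  inside <- s$mz >= center_mz - width / 2 & s$mz < center_mz + width / 2
  ranked <- rank_window(s$intensity[inside], min_peaks = min_peaks)
  fit <- fit_power(ranked, min_peaks = min_peaks)
  knee <- find_knee(fit)
  grid <- tibble::tibble(rank = seq(1, fit$n, length.out = 512))
  grid$intensity <- power_curve(fit, grid$rank)
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::annotate("point", x = knee$rank, y = knee$value,
                      colour = "blue", size = 3, shape = 17) +
    ggplot2::labs(x = "rank", y = "intensity (a.u.)",
                  title = sprintf("Window %g +/- %g: R^2 = %.4f, knee at rank %.1f",
                                  center_mz, width / 2, fit$r2, knee$rank))
}
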