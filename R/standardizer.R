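#' Sliding-window knee normalization points
#'
#' Slides a window of `width` Thomson across the spectrum in steps of
#' `step` Thomson, computing the knee normalization value of each window
#' (see [window_knee_value()]).  Window centers start at
#' `min(mz) + width/2` and advance while the window still fits inside the
#' spectrum, so no normalization point exists within `width/2` of either
#' edge.  Windows that fail occupancy or the fit are omitted (the spline
#' bridges the gaps); at least 4 surviving points are required.
#'
#' @param spectrum A spectrum or peak data frame whose m/z span is at
#'   least `width`.
#' @param width Window width in Thomson (default 50).
#' @param step Window shift in Thomson (default 1).
#' @param min_peaks Minimum window occupancy (default 20).
#' @return A tibble of surviving normalization points, columns
#'   `center_mz` and `value` plus per-window fit diagnostics; omitted
#'   windows are kept in the `"failures"` attribute.
#' @export
compute_normalization_points <- function(spectrum, width = 50, step = 1,
                                         min_peaks = 20) {
  stopifnot(width > 0, step > 0)
  s <- as_spectrum(spectrum)
  lo <- min(s$mz); hi <- max(s$mz)
  if (hi - lo < width) {
    abort(sprintf("m/z span %.4g is smaller than the window width %g", hi - lo, width),
          class = "kneescale_precondition_error")
  }
  centers <- seq(lo + width / 2, hi - width / 2, by = step)
  rows <- purrr::map(centers, function(cc) {
    window_knee_value(s, cc, width = width, min_peaks = min_peaks)
  })
  all_rows <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(all_rows, .data$status == "ok")
  failed <- dplyr::filter(all_rows, .data$status != "ok")
  if (nrow(failed) > 0) {
    inform(sprintf("%d of %d windows yielded no normalization point (%s)",
                   nrow(failed), nrow(all_rows),
                   paste(sprintf("%s: %d", names(table(failed$status)),
                                 table(failed$status)), collapse = ", ")))
  }
  if (nrow(ok) < 4) {
    abort(sprintf("standardization infeasible: only %d viable normalization point(s), need >= 4",
                  nrow(ok)),
          class = "kneescale_infeasible_error")
  }
  attr(ok, "failures") <- failed
  ok
}

#' Fit the normalization curve through knee points
#'
#' A smoothing spline through the (center m/z, knee value) points.  The
#' smoothness is chosen by generalized cross-validation; if the residual
#' standard deviation against the points exceeds `max_resid_frac` of the
#' points' median value, the smoothing is tightened (equivalent degrees of
#' freedom increased) until the bound holds.  The curve must stay strictly
#' positive over its support; evaluation outside the support clamps to the
#' endpoint value (spline extrapolation is unstable).
#'
#' @param points A tibble with columns `center_mz` and `value` (strictly
#'   increasing centers, >= 4 rows), e.g. from
#'   [compute_normalization_points()].
#' @param max_resid_frac Residual bound as a fraction of the median point
#'   value (default 0.15).
#' @param df Optional fixed equivalent degrees of freedom, bypassing GCV.
#' @return A `normalization_curve` object, evaluable with
#'   [predict.normalization_curve()].
#' @export
fit_normalization_curve <- function(points, max_resid_frac = 0.15, df = NULL) {
  stopifnot(is.data.frame(points), all(c("center_mz", "value") %in% names(points)))
  x <- points$center_mz; y <- points$value
  if (length(x) < 4) {
    abort("need at least 4 normalization points", class = "kneescale_infeasible_error")
  }
  if (any(diff(x) <= 0)) {
    abort("normalization point centers must be strictly increasing",
          class = "kneescale_precondition_error")
  }
  if (any(!is.finite(y) | y <= 0)) {
    abort("normalization values must be positive and finite",
          class = "kneescale_precondition_error")
  }

  med <- median(y)
  if ((max(y) - min(y)) <= 1e-12 * med) {
    # constant data: spline is the constant
    return(structure(list(points = tibble::as_tibble(points[c("center_mz", "value")]),
                          fit = NULL, constant = med, range = range(x)),
                     class = "normalization_curve"))
  }

  fit <- if (is.null(df)) smooth.spline(x, y, cv = FALSE) else smooth.spline(x, y, df = df)
  bound <- max_resid_frac * med
  resid_sd <- function(f) sqrt(mean((y - predict(f, x = x)$y)^2))
  cur_df <- fit$df
  while (resid_sd(fit) > bound && cur_df < length(x) - 1e-6) {
    cur_df <- min(cur_df * 1.4 + 1, length(x))
    fit <- smooth.spline(x, y, df = cur_df)
  }
  if (resid_sd(fit) > bound) {
    warn(sprintf("normalization curve residual sd %.3g exceeds %g%% of the median point value",
                 resid_sd(fit), 100 * max_resid_frac))
  }
  grid <- seq(min(x), max(x), length.out = 1024)
  if (any(predict(fit, x = grid)$y <= 0)) {
    abort("normalization curve dips to zero or below on its support; increase the smoothing parameter (df) or widen windows",
          class = "kneescale_curve_error")
  }
  structure(list(points = tibble::as_tibble(points[c("center_mz", "value")]),
                 fit = fit, constant = NULL, range = range(x)),
            class = "normalization_curve")
}

#' Evaluate a normalization curve
#'
#' @param object A `normalization_curve`.
#' @param mz Numeric vector of m/z values; values outside the support are
#'   clamped to the nearest endpoint.
#' @param ... Unused.
#' @return Numeric vector of positive curve values.
#' @export
predict.normalization_curve <- function(object, mz, ...) {
  mz <- pmin(pmax(as.numeric(mz), object$range[1]), object$range[2])
  if (!is.null(object$constant)) return(rep(object$constant, length(mz)))
  predict(object$fit, x = mz)$y
}

#' @export
print.normalization_curve <- function(x, ...) {
  cat(sprintf("Normalization curve: %d knee points over m/z %.4g-%.4g%s\n",
              nrow(x$points), x$range[1], x$range[2],
              if (is.null(x$constant)) "" else " (constant)"))
  invisible(x)
}

#' Divide a spectrum by its normalization curve
#'
#' Each peak's intensity is divided by the curve value at the peak's m/z,
#' yielding dimensionless standardized intensities; m/z values and peak
#' count are untouched and the scale tag becomes `"standardized"`.
#'
#' @param spectrum A spectrum or peak data frame.
#' @param curve A `normalization_curve`, normally built from this same
#'   spectrum (set `allow_foreign = TRUE` to apply a curve built
#'   elsewhere).
#' @param allow_foreign Permit a curve whose support does not match the
#'   spectrum.
#' @return The standardized spectrum.
#' @export
standardize_spectrum <- function(spectrum, curve, allow_foreign = FALSE) {
  stopifnot(inherits(curve, "normalization_curve"))
  s <- as_spectrum(spectrum)
  if (!allow_foreign &&
      (curve$range[1] < min(s$mz) - 1e-6 || curve$range[2] > max(s$mz) + 1e-6)) {
    abort("curve support extends beyond the spectrum; pass allow_foreign = TRUE to apply a curve built from another spectrum",
          class = "kneescale_precondition_error")
  }
  v <- predict(curve, s$mz)
  if (any(!is.finite(v) | v <= 0)) {
    abort("normalization curve evaluated non-positive at a peak m/z",
          class = "kneescale_internal_error")
  }
  new_spectrum(tibble::tibble(mz = s$mz, intensity = s$intensity / v),
               label = spectrum_label(s), scale = "standardized")
}

#' Standardize a spectrum end-to-end
#'
#' Convenience composition: compute the sliding-window knee points, fit
#' the smoothing-spline normalization curve, and divide the spectrum by
#' it.  The result is invariant under uniform intensity rescaling of the
#' input (`standardize(alpha * S)` equals `standardize(S)` to float
#' precision for any alpha > 0).
#'
#' @inheritParams compute_normalization_points
#' @inheritParams fit_normalization_curve
#' @return A list of class `standardization` with elements `spectrum`
#'   (the standardized spectrum) and `curve` (the normalization curve,
#'   whose `points` carry the per-window diagnostics).
#' @examples
#' s <- simulate_plasma_spectrum(n_peaks = 2000, mz_range = c(225, 325), seed = 1)
#' out <- standardize(s)
#' out$spectrum
#' @export
standardize <- function(spectrum, width = 50, step = 1, min_peaks = 20,
                        max_resid_frac = 0.15, df = NULL) {
  s <- as_spectrum(spectrum)
  pts <- compute_normalization_points(s, width = width, step = step,
                                      min_peaks = min_peaks)
  curve <- fit_normalization_curve(pts, max_resid_frac = max_resid_frac, df = df)
  std <- standardize_spectrum(s, curve)
  structure(list(spectrum = std, curve = curve, diagnostics = pts),
            class = "standardization")
}

#' @export
print.standardization <- function(x, ...) {
  print(x$curve)
  print(x$spectrum, n = 5)
  invisible(x)
}
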