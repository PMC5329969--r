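#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects.
#'
#' * `tidy.power_fit()` — one row per parameter (a, b, c).
#' * `glance.power_fit()` — one row: a, b, c, r2, n.
#' * `tidy.knee_point()` — one row: rank, value.
#' * `tidy.normalization_curve()` — one row per knee point with the spline
#'   value at its center.
#' * `tidy.knee_stability()` — one row per noise replicate.
#' * `glance.knee_stability()` — knee CV, mean, sd, counts.
#' * `tidy.spectra_concordance()` — one row per statistic with confidence
#'   limits where available.
#' * `glance.spectra_concordance()` — all statistics in one row.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name kneescale-tidiers
NULL

#' @rdname kneescale-tidiers
#' @export
tidy.power_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname kneescale-tidiers
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, r2 = x$r2, n = x$n)
}

#' @rdname kneescale-tidiers
#' @export
tidy.knee_point <- function(x, ...) {
  tibble::tibble(rank = x$rank, value = x$value)
}

#' @rdname kneescale-tidiers
#' @export
tidy.normalization_curve <- function(x, ...) {
  dplyr::mutate(x$points, spline_value = predict(x, x$points$center_mz))
}

#' @rdname kneescale-tidiers
#' @export
tidy.knee_stability <- function(x, ...) {
  x$replicates
}

#' @rdname kneescale-tidiers
#' @export
glance.knee_stability <- function(x, ...) {
  tibble::tibble(knee_cv = x$knee_cv, mean = mean(x$values),
                 sd = sd(x$values), n = length(x$values),
                 n_failed = x$n_failed, intensity_cv = x$cv,
                 center_mz = x$center_mz, width = x$width)
}

#' @rdname kneescale-tidiers
#' @export
tidy.spectra_concordance <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "r2", "pearson_r", "spearman_rho",
             "pb_slope", "pb_intercept"),
    estimate = c(x$linear$slope, x$linear$intercept, x$linear$r2,
                 x$linear$pearson_r, x$linear$spearman_rho,
                 x$pb$pb_slope, x$pb$pb_intercept),
    conf.low = c(NA, NA, NA, NA, NA, x$pb$pb_slope_lo, x$pb$pb_intercept_lo),
    conf.high = c(NA, NA, NA, NA, NA, x$pb$pb_slope_hi, x$pb$pb_intercept_hi)
  )
}

#' @rdname kneescale-tidiers
#' @export
glance.spectra_concordance <- function(x, ...) {
  dplyr::bind_cols(
    x$linear[c("slope", "intercept", "r2", "pearson_r", "spearman_rho")],
    x$pb[c("pb_slope", "pb_intercept", "pb_slope_lo", "pb_slope_hi",
           "pb_intercept_lo", "pb_intercept_hi")],
    tibble::tibble(n_matched = x$n_matched,
                   n_unmatched_x = x$n_unmatched_x,
                   n_unmatched_y = x$n_unmatched_y)
  )
}
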