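#' Simulate a plasma-like direct-infusion spectrum
#'
#' Draws `n_peaks` peak positions uniformly over `mz_range` and intensities
#' from a truncated Pareto-like law, `intensity = amplitude *
#' u^(-tail_exponent) + baseline` with `u ~ Uniform(u_min, 1)`.  Because
#' the order statistics of a uniform sample are approximately `i/(n+1)`,
#' the descending intensities of any m/z window follow `y = a * x^b + c`
#' with `b = -tail_exponent` almost exactly, reproducing the power-law
#' rank-intensity decay of blood-plasma metabolite fingerprints; the
#' truncation `u_min > 0` bounds the most abundant substance, as a real
#' biofluid's composition does, and with the default density keeps every
#' 50-Th window's power fit at R^2 >= 0.98.
#'
#' @param n_peaks Number of peaks (>= 100; default 40000, giving the peak
#'   density per 50-Th window at which window fits reach the fidelity of
#'   real direct-infusion plasma fingerprints).
#' @param mz_range Length-2 numeric, m/z limits in Thomson (default
#'   c(225, 425)).
#' @param amplitude Amplitude of the intensity law (instrument units,
#'   default 1000).
#' @param tail_exponent Pareto tail exponent (> 0, default 0.25).
#' @param baseline Additive intensity offset (default 10).
#' @param u_min Lower truncation of the abundance variable (default 2e-4;
#'   0 recovers the unbounded law).
#' @param label Label of the returned spectrum.
#' @param seed Optional integer seed; the same seed reproduces the
#'   spectrum bit for bit and the caller's RNG state is untouched.
#' @return A raw-scale spectrum tibble.
#' @export
simulate_plasma_spectrum <- function(n_peaks = 40000, mz_range = c(225, 425),
                                     amplitude = 1000, tail_exponent = 0.25,
                                     baseline = 10, u_min = 2e-4,
                                     label = "simulated plasma",
                                     seed = NULL) {
  stopifnot(n_peaks >= 100, length(mz_range) == 2, mz_range[1] < mz_range[2],
            tail_exponent > 0, amplitude > 0, baseline >= 0,
            u_min >= 0, u_min < 1)
  draw <- function() {
    mz <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
    u <- runif(n_peaks, u_min, 1)
    tibble::tibble(mz = mz, intensity = amplitude * u^(-tail_exponent) + baseline)
  }
  df <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_spectrum(df, label = label, scale = "raw")
}

#' Perturb intensities with multiplicative biological noise
#'
#' Each intensity is multiplied by an independent Gaussian factor with
#' mean 1 and standard deviation `cv`, emulating the biological
#' between-replicate variation of plasma metabolite levels (average CV of
#' 46% is the literature figure for plasma).  Factors are truncated below
#' at `floor` so that intensities cannot become non-positive (at CV 46%
#' a Gaussian factor is negative roughly 1.5% of the time).
#'
#' @param spectrum A spectrum or peak data frame.
#' @param cv Target coefficient of variation of each intensity (fraction;
#'   default 0.46).  `cv = 0` returns the input unchanged.
#' @param floor Minimum retained fraction of the original intensity
#'   (default 0.01).
#' @param seed Optional integer seed (caller's RNG state untouched).
#' @return A spectrum with perturbed intensities.
#' @export
add_intensity_noise <- function(spectrum, cv = 0.46, floor = 0.01, seed = NULL) {
  stopifnot(cv >= 0, floor > 0, floor < 1)
  s <- as_spectrum(spectrum)
  if (cv == 0) return(s)
  draw <- function() pmax(rnorm(nrow(s), mean = 1, sd = cv), floor)
  f <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_spectrum(tibble::tibble(mz = s$mz, intensity = s$intensity * f),
               label = spectrum_label(s), scale = spectrum_scale(s))
}

#' Distortion factor profile over m/z
#'
#' The multiplicative factor applied at each m/z by the three distortion
#' models used to validate standardization:
#' * `uniform` — constant `factor` (default 10) everywhere;
#' * `ramp` — linear from `f_lo` (default 1) at the low-m/z edge to
#'   `f_hi` (default 10) at the high edge;
#' * `gaussian` — `f_edge + (f_center - f_edge) * exp(-(mz - mid)^2 /
#'   (2 * sigma^2))` with `sigma = width_frac * span`, so the center of
#'   the spectrum is amplified (default 4x) while the edges are suppressed
#'   (default 1/4x).
#'
#' @param mz Numeric vector of m/z values.
#' @param kind `"uniform"`, `"ramp"` or `"gaussian"`.
#' @param factor Uniform factor.
#' @param f_lo,f_hi Ramp edge factors.
#' @param f_edge,f_center Gaussian edge/center factors.
#' @param width_frac Gaussian sigma as a fraction of the m/z span
#'   (default 1/6, placing the edge factors near `f_edge`).
#' @param mz_range m/z limits defining the edges (default `range(mz)`).
#' @return Numeric vector of positive factors, one per m/z.
#' @export
distortion_factors <- function(mz, kind = c("uniform", "ramp", "gaussian"),
                               factor = 10, f_lo = 1, f_hi = 10,
                               f_edge = 0.25, f_center = 4, width_frac = 1 / 6,
                               mz_range = range(mz)) {
  kind <- match.arg(kind)
  stopifnot(all(c(factor, f_lo, f_hi, f_edge, f_center) > 0), width_frac > 0)
  lo <- mz_range[1]; hi <- mz_range[2]
  switch(kind,
    uniform = rep(factor, length(mz)),
    ramp = f_lo + (f_hi - f_lo) * (mz - lo) / (hi - lo),
    gaussian = {
      sigma <- width_frac * (hi - lo)
      mid <- (lo + hi) / 2
      f_edge + (f_center - f_edge) * exp(-(mz - mid)^2 / (2 * sigma^2))
    }
  )
}

#' Apply an instrument-like distortion to a spectrum
#'
#' Multiplies every intensity by the factor profile of
#' [distortion_factors()]; m/z values are untouched.  The three models
#' imitate the kinds of undesired variability met in practice: a uniform
#' sensitivity change, a linear drift across the mass range, and a
#' nonlinear (Gaussian) response.  Each distortion is exactly invertible
#' by dividing by the same factors.
#'
#' @inheritParams distortion_factors
#' @param spectrum A spectrum or peak data frame.
#' @param ... Passed to [distortion_factors()] (`factor`, `f_lo`, `f_hi`,
#'   `f_edge`, `f_center`, `width_frac`).
#' @return The distorted spectrum (same scale tag as the input).
#' @export
apply_distortion <- function(spectrum, kind = c("uniform", "ramp", "gaussian"),
                             ...) {
  kind <- match.arg(kind)
  s <- as_spectrum(spectrum)
  f <- distortion_factors(s$mz, kind = kind, mz_range = range(s$mz), ...)
  new_spectrum(tibble::tibble(mz = s$mz, intensity = s$intensity * f),
               label = spectrum_label(s), scale = spectrum_scale(s))
}

#' Knee-point stability under biological noise
#'
#' Repeatedly perturbs a spectrum with multiplicative Gaussian noise of a
#' given per-peak CV, extracts one window's knee value from each
#' replicate, and reports the coefficient of variation of the knee value
#' across replicates.  A stable knee (CV far below the per-peak CV) is
#' what qualifies it as an internal standard.
#'
#' @param spectrum A spectrum or peak data frame; the chosen window must
#'   be viable on it.
#' @param cv Per-peak intensity CV of the noise (default 0.46).
#' @param iterations Number of noise replicates (default 10).
#' @param center Window center in Thomson; default the midpoint of the
#'   spectrum's m/z range.
#' @param width Window width (default 50).
#' @param floor Noise truncation floor (default 0.01).
#' @param seed Integer seed; replicate i uses seed `seed + i`, so growing
#'   `iterations` keeps the earlier replicate values identical.
#' @param min_peaks Minimum window occupancy.
#' @param max_fail_frac The experiment errors if more than this fraction
#'   of replicates fails to yield a knee (default 0.2).
#' @return A `knee_stability` object: list with `knee_cv` (sd/mean,
#'   fraction), `values` (replicate knee values), `n_failed`, and the
#'   replicate table.
#' @export
knee_stability <- function(spectrum, cv = 0.46, iterations = 10,
                           center = NULL, width = 50, floor = 0.01,
                           seed = 1, min_peaks = 20, max_fail_frac = 0.2) {
  stopifnot(iterations >= 2)
  s <- as_spectrum(spectrum)
  center <- center %||% mean(range(s$mz))
  base <- window_knee_value(s, center, width = width, min_peaks = min_peaks)
  if (base$status != "ok") {
    abort(sprintf("window at center %.4g is not viable on the base spectrum (%s)",
                  center, base$status),
          class = "kneescale_precondition_error")
  }
  reps <- purrr::map(seq_len(iterations), function(i) {
    noisy <- add_intensity_noise(s, cv = cv, floor = floor, seed = seed + i)
    row <- window_knee_value(noisy, center, width = width, min_peaks = min_peaks)
    tibble::tibble(iteration = i, value = row$value, status = row$status)
  })
  reps <- dplyr::bind_rows(reps)
  n_failed <- sum(reps$status != "ok")
  if (n_failed > max_fail_frac * iterations) {
    abort(sprintf("knee stability experiment failed: %d of %d replicates did not yield a knee",
                  n_failed, iterations),
          class = "kneescale_fit_error")
  }
  vals <- reps$value[reps$status == "ok"]
  structure(list(knee_cv = sd(vals) / mean(vals), values = vals,
                 n_failed = n_failed, replicates = reps,
                 center_mz = center, width = width, cv = cv,
                 base_value = base$value),
            class = "knee_stability")
}

#' @export
print.knee_stability <- function(x, ...) {
  cat(sprintf("Knee stability: window center %.4g (width %g), intensity CV %.0f%% -> knee CV %.2f%% over %d replicate(s)%s\n",
              x$center_mz, x$width, 100 * x$cv, 100 * x$knee_cv,
              length(x$values),
              if (x$n_failed > 0) sprintf(" (%d failed)", x$n_failed) else ""))
  invisible(x)
}
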