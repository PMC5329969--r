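#' Rank a window's intensities in descending order
#'
#' Within a sliding m/z window the peak intensities are arranged in
#' decreasing order before the power-curve fit.  Ties are broken by input
#' position (stable sort), which for window extraction means ascending
#' m/z — deterministic across runs.
#'
#' @param intensities Numeric vector of positive intensities.
#' @param min_peaks Minimum window occupancy (default 20): a 3-parameter
#'   nonlinear fit plus curvature maximization is unstable below that.
#' @return A tibble with columns `rank` (1..n) and `intensity`
#'   (non-increasing).
#' @export
rank_window <- function(intensities, min_peaks = 20) {
  intensities <- as.numeric(intensities)
  if (any(!is.finite(intensities) | intensities <= 0)) {
    abort("intensities must be positive and finite", class = "kneescale_ingest_error")
  }
  if (length(intensities) < min_peaks) {
    abort(sprintf("window occupancy %d below minimum %d",
                  length(intensities), min_peaks),
          class = "kneescale_occupancy_error")
  }
  ord <- order(-intensities)  # stable: ties keep input (ascending m/z) order
  tibble::tibble(rank = seq_along(intensities), intensity = intensities[ord])
}

#' Fit the power curve to rank-ordered intensities
#'
#' Least-squares fit of `y = a * x^b + c` (a > 0, b < 0, c >= 0) to a
#' window's descending intensities by Levenberg-Marquardt with box bounds.
#' Start values follow the curve's endpoints (`a0 = y1 - yn`, `b0 = -1`,
#' `c0 = yn`).  Intensities are scaled by the window maximum before the
#' fit and the amplitude/offset rescaled afterwards, so the estimates are
#' equivariant under intensity rescaling to float precision — the property
#' that makes the downstream standardization exactly scale-invariant.
#'
#' @param ranked A tibble from [rank_window()], or a bare numeric vector of
#'   intensities (ranked internally).
#' @param min_peaks Minimum number of points.
#' @param max_iter Iteration budget for the optimizer.
#' @param tol Convergence tolerance (relative reduction in the sum of
#'   squares).
#' @return A `power_fit` object: list with `a`, `b`, `c`, `r2` (coefficient
#'   of determination against the ranked data) and `n`.
#' @export
fit_power <- function(ranked, min_peaks = 20, max_iter = 1000, tol = 1e-8) {
  if (is.numeric(ranked)) ranked <- rank_window(ranked, min_peaks = min_peaks)
  stopifnot(is.data.frame(ranked), all(c("rank", "intensity") %in% names(ranked)))
  y <- ranked$intensity
  x <- as.numeric(ranked$rank)
  n <- length(y)
  if (n < min_peaks) {
    abort(sprintf("window occupancy %d below minimum %d", n, min_peaks),
          class = "kneescale_occupancy_error")
  }
  if ((max(y) - min(y)) / max(y) < 1e-9) {
    abort("degenerate window: intensities are (near-)constant",
          class = "kneescale_degenerate_window_error")
  }

  ymax <- y[1]
  ys <- y / ymax
  sse <- function(p) sum((ys - (p[1] * x^p[2] + p[3]))^2)

  # Profiled exponent first: for fixed b the model is linear in (a, c), so
  # the conditional least-squares solution is exact; minimizing over b alone
  # is immune to the flat local minima a full 3-parameter descent can fall
  # into on shallow curves, and leaves only a short polish for LM.
  cand <- profile_power_fit(ys, x)
  if (is.null(cand)) {
    abort("power fit failed to converge", class = "kneescale_fit_error")
  }
  polish <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ a * x^b + c,
      start = list(a = cand[1], b = cand[2], c = cand[3]),
      lower = c(a = 1e-12, b = -10, c = 0),
      upper = c(a = Inf, b = -1e-8, c = Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1024), ftol = tol, ptol = tol
      )
    ),
    error = function(e) NULL
  )
  if (!is.null(polish)) {
    p2 <- unname(coef(polish)[c("a", "b", "c")])
    if (sse(p2) < sse(cand)) cand <- p2
  }

  a <- cand[1] * ymax
  b <- cand[2]
  c0 <- cand[3] * ymax
  yhat <- a * x^b + c0
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(list(a = a, b = b, c = c0, r2 = r2, n = n), class = "power_fit")
}

# Conditional-linear profile of the power model: exact (a, c) for fixed b
# (2x2 normal equations, constraints a > 0, c >= 0 by clamping), exponent
# then located by a coarse grid plus bounded refinement.
profile_power_fit <- function(ys, x) {
  solve_ac <- function(b) {
    f <- x^b
    sf <- sum(f); sf2 <- sum(f * f); sy <- sum(ys); sfy <- sum(f * ys)
    n <- length(x)
    den <- n * sf2 - sf * sf
    if (den <= 0) return(NULL)
    a <- (n * sfy - sf * sy) / den
    c0 <- (sy - a * sf) / n
    if (c0 < 0) { c0 <- 0; a <- sfy / sf2 }
    if (a <= 0) return(NULL)
    c(a, b, c0)
  }
  obj <- function(b) {
    p <- solve_ac(b)
    if (is.null(p)) return(Inf)
    sum((ys - (p[1] * x^p[2] + p[3]))^2)
  }
  b_grid <- -exp(seq(log(0.02), log(8), length.out = 40))
  vals <- vapply(b_grid, obj, numeric(1))
  if (all(!is.finite(vals))) return(NULL)
  i <- which.min(vals)
  lo <- b_grid[min(i + 1, length(b_grid))]  # grid is descending in |b|
  hi <- b_grid[max(i - 1, 1)]
  opt <- optimize(obj, lower = min(lo, hi), upper = max(lo, hi), tol = 1e-9)
  solve_ac(opt$minimum)
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power fit y = a*x^b + c: a = %.6g, b = %.6g, c = %.6g (n = %d, R^2 = %.4f)\n",
              x$a, x$b, x$c, x$n, x$r2))
  invisible(x)
}

power_curve <- function(fit, x) fit$a * x^fit$b + fit$c

#' Locate the knee (maximum-curvature) point of a fitted power curve
#'
#' The knee is the maximum of the plane-curve curvature
#' `kappa = |y''| / (1 + y'^2)^(3/2)` of the *axis-normalized* fitted
#' curve: x rescaled to (0, 1] by the window size n and y rescaled to
#' [0, 1] by its range over ranks 1..n.  Normalizing the axes makes the
#' knee rank invariant and the knee value equivariant under intensity
#' rescaling, which is what lets the standardization cancel a uniform
#' distortion exactly.  Derivatives are analytic; the argmax is located by
#' a 1000-point grid seeded bounded search (tolerance 1e-6 in normalized
#' x).
#'
#' @param fit A `power_fit`.
#' @param n Window size (number of ranked points); defaults to `fit$n`.
#' @param min_peaks Minimum admissible n.
#' @return A `knee_point` object: list with `rank` (continuous, in (1, n))
#'   and `value` (the un-normalized fitted intensity `a*rank^b + c`).
#' @export
find_knee <- function(fit, n = fit$n, min_peaks = 20) {
  stopifnot(inherits(fit, "power_fit"))
  if (is.null(n) || n < min_peaks) {
    abort(sprintf("window size %s below minimum %d", n %||% NA, min_peaks),
          class = "kneescale_occupancy_error")
  }
  a <- fit$a; b <- fit$b; c0 <- fit$c
  yrange <- a * (1 - n^b)  # y(1) - y(n), > 0 for a > 0, b < 0
  if (!is.finite(yrange) || yrange <= 0) {
    abort("fitted curve is not decreasing; knee undefined",
          class = "kneescale_knee_error")
  }
  # normalized curve g(t) = (y(n t) - y(n)) / yrange, t in [1/n, 1]
  kappa <- function(t) {
    x <- n * t
    g1 <- a * b * x^(b - 1) * n / yrange
    g2 <- a * b * (b - 1) * x^(b - 2) * n^2 / yrange
    abs(g2) / (1 + g1^2)^1.5
  }
  lo <- 1 / n
  grid <- seq(lo, 1, length.out = 1000)
  kv <- kappa(grid)
  i <- which.max(kv)
  if (i == 1 || i == length(grid)) {
    abort("curvature has no interior maximum; knee not found",
          class = "kneescale_knee_error")
  }
  opt <- optimize(kappa, lower = grid[i - 1], upper = grid[i + 1],
                  maximum = TRUE, tol = 1e-6)
  rank <- opt$maximum * n
  if (rank <= 1 || rank >= n) {
    abort("knee rank fell outside the interior of the window",
          class = "kneescale_knee_error")
  }
  structure(list(rank = rank, value = power_curve(fit, rank),
                 curvature = opt$objective),
            class = "knee_point")
}

#' @export
print.knee_point <- function(x, ...) {
  cat(sprintf("Knee point: rank %.2f, value %.6g\n", x$rank, x$value))
  invisible(x)
}

#' Knee normalization value of one m/z window
#'
#' Collects the peaks with m/z in the half-open window
#' `[center - width/2, center + width/2)`, ranks them, fits the power
#' curve and locates its knee.  A window that fails occupancy, the fit, or
#' knee detection is not an error: it yields an "absent" row whose
#' `status` column records the reason, so that sliding-window callers can
#' bridge the gap with the spline.
#'
#' @param spectrum A spectrum or peak data frame.
#' @param center_mz Window center (Thomson).
#' @param width Window width (Thomson), default 50.
#' @param min_peaks Minimum window occupancy, default 20.
#' @return A one-row tibble: `center_mz`, `value` (knee intensity, `NA` if
#'   absent), `status` (`"ok"`, `"occupancy"`, `"degenerate"`,
#'   `"fit_error"`, `"knee_error"`), `n_peaks`, and fit diagnostics
#'   (`a`, `b`, `c`, `r2`, `knee_rank`).
#' @export
window_knee_value <- function(spectrum, center_mz, width = 50, min_peaks = 20) {
  stopifnot(width > 0)
  s <- as_spectrum(spectrum)
  inside <- s$mz >= center_mz - width / 2 & s$mz < center_mz + width / 2
  y <- s$intensity[inside]
  absent <- function(status) {
    tibble::tibble(center_mz = center_mz, value = NA_real_, status = status,
                   n_peaks = length(y), a = NA_real_, b = NA_real_,
                   c = NA_real_, r2 = NA_real_, knee_rank = NA_real_)
  }
  if (length(y) < min_peaks) return(absent("occupancy"))
  fit <- tryCatch(fit_power(rank_window(y, min_peaks), min_peaks = min_peaks),
                  kneescale_degenerate_window_error = function(e) "degenerate",
                  kneescale_fit_error = function(e) "fit_error")
  if (is.character(fit)) return(absent(fit))
  knee <- tryCatch(find_knee(fit, min_peaks = min_peaks),
                   kneescale_knee_error = function(e) NULL)
  if (is.null(knee)) return(absent("knee_error"))
  tibble::tibble(center_mz = center_mz, value = knee$value, status = "ok",
                 n_peaks = length(y), a = fit$a, b = fit$b, c = fit$c,
                 r2 = fit$r2, knee_rank = knee$rank)
}
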