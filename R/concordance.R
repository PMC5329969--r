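#' Match peaks between two spectra by m/z
#'
#' Greedy nearest-neighbor matching within an absolute m/z tolerance,
#' resolved globally by ascending |delta m/z| (ties broken by m/z for
#' determinism); each peak of either spectrum appears in at most one
#' pair, and `match_peaks(a, b)` mirrors `match_peaks(b, a)`.
#'
#' @param a,b Spectra or peak data frames.
#' @param tol Matching tolerance: Thomson by default, parts-per-million if
#'   `ppm = TRUE` (relative to the mean of the candidate pair).  `tol = 0`
#'   matches exact m/z equality only.
#' @param ppm Interpret `tol` in ppm.
#' @return A `paired_intensities` tibble with columns `mz_x`, `mz_y`, `x`,
#'   `y`, `dmz`; the counts of unmatched peaks are in attributes
#'   `n_unmatched_x` / `n_unmatched_y`.
#' @export
match_peaks <- function(a, b, tol = 0.005, ppm = FALSE) {
  stopifnot(tol >= 0)
  sa <- as_spectrum(a); sb <- as_spectrum(b)
  # candidate pairs within tolerance, via interval lookup on the sorted b grid
  cand_i <- integer(0); cand_j <- integer(0)
  mzb <- sb$mz
  for (i in seq_len(nrow(sa))) {
    t_abs <- if (ppm) tol * 1e-6 * sa$mz[i] else tol
    lo <- findInterval(sa$mz[i] - t_abs, mzb, left.open = TRUE) + 1
    hi <- findInterval(sa$mz[i] + t_abs, mzb)
    if (hi >= lo) {
      cand_i <- c(cand_i, rep(i, hi - lo + 1))
      cand_j <- c(cand_j, lo:hi)
    }
  }
  pairs <- tibble::tibble(i = cand_i, j = cand_j,
                          dmz = abs(sa$mz[cand_i] - mzb[cand_j]))
  pairs <- pairs[order(pairs$dmz, sa$mz[pairs$i], mzb[pairs$j]), ]
  used_a <- logical(nrow(sa)); used_b <- logical(nrow(sb))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  m <- pairs[keep, ]
  m <- m[order(sa$mz[m$i]), ]
  out <- tibble::tibble(mz_x = sa$mz[m$i], mz_y = mzb[m$j],
                        x = sa$intensity[m$i], y = sb$intensity[m$j],
                        dmz = m$dmz)
  structure(out, class = c("paired_intensities", class(out)),
            n_unmatched_x = sum(!used_a), n_unmatched_y = sum(!used_b))
}

#' Linear concordance statistics for paired intensities
#'
#' Ordinary least squares of y on x, the coefficient of determination,
#' Pearson correlation on raw intensities and Spearman rank correlation
#' (midrank ties).
#'
#' @param pairs A data frame with columns `x` and `y` (>= 3 rows), e.g.
#'   from [match_peaks()].
#' @return A one-row tibble: `slope`, `intercept`, `r2`, `pearson_r`,
#'   `spearman_rho`, `n`.
#' @export
linear_concordance <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
  x <- pairs$x; y <- pairs$y
  if (length(x) < 3) {
    abort("need at least 3 matched pairs", class = "kneescale_precondition_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y: concordance statistics undefined",
          class = "kneescale_degenerate_window_error")
  }
  fit <- lm(y ~ x)
  pearson <- cor(x, y)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = pearson^2,  # R^2 of simple OLS is the squared Pearson correlation
    pearson_r = pearson,
    spearman_rho = cor(x, y, method = "spearman"),
    n = length(x)
  )
}

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes `S_ij = (y_j - y_i)/(x_j - x_i)` (i < j),
#' where slopes exactly equal to -1 are discarded and the median index is
#' offset by `K`, the number of slopes below -1; the intercept is
#' `median(y - slope * x)`.  Confidence intervals use the rank-based
#' normal approximation with
#' `C = z * sqrt(n (n - 1) (2 n + 5) / 18)`.  Slope 1 / intercept 0
#' indicates interchangeable measurement scales.
#'
#' For very large matched sets the O(n^2) slope enumeration is capped by
#' subsampling `max_pairs` pairs with a fixed seed; sets up to `max_pairs`
#' are enumerated in full.
#'
#' @param pairs A data frame with columns `x` and `y` (>= 10 rows, x not
#'   all equal).
#' @param conf Confidence level (default 0.95).
#' @param max_pairs Subsampling cap (default 5000).
#' @param subsample_seed Seed used only when subsampling.
#' @return A one-row tibble: `pb_slope`, `pb_intercept`, `pb_slope_lo`,
#'   `pb_slope_hi`, `pb_intercept_lo`, `pb_intercept_hi`, `n`.
#' @export
passing_bablok <- function(pairs, conf = 0.95, max_pairs = 5000,
                           subsample_seed = 20170228) {
  stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  if (n < 10) {
    abort("need at least 10 matched pairs for Passing-Bablok",
          class = "kneescale_precondition_error")
  }
  if (max(x) == min(x)) {
    abort("all x values equal: Passing-Bablok slope undefined",
          class = "kneescale_degenerate_window_error")
  }
  if (n > max_pairs) {
    idx <- withr::with_seed(subsample_seed, sample.int(n, max_pairs))
    x <- x[sort(idx)]; y <- y[sort(idx)]
    n <- max_pairs
  }

  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  up <- upper.tri(dx)
  S <- dy[up] / dx[up]
  S <- S[!is.nan(S)]         # 0/0 pairs (identical points) carry no information
  S <- S[S != -1]            # slopes of exactly -1 discarded per the estimator
  S <- sort(S)               # sorts finite values; +/-Inf fall at the ends
  N <- length(S)
  if (N < 1) {
    abort("too few informative pairwise slopes", class = "kneescale_degenerate_window_error")
  }
  K <- sum(S < -1)
  mid_idx <- function(shift) {
    if (N %% 2 == 1) S[(N + 1) / 2 + shift] else mean(S[N / 2 + shift + c(0, 1)])
  }
  if ((N %% 2 == 1 && (N + 1) / 2 + K > N) || (N %% 2 == 0 && N / 2 + K + 1 > N)) {
    abort("shifted median index out of range; data unsuitable for Passing-Bablok",
          class = "kneescale_degenerate_window_error")
  }
  b <- mid_idx(K)
  z <- qnorm(1 - (1 - conf) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- ceiling((N - C) / 2); M2 <- N - M1 + 1
  b_lo <- if (M1 + K >= 1 && M1 + K <= N) S[M1 + K] else NA_real_
  b_hi <- if (M2 + K >= 1 && M2 + K <= N) S[M2 + K] else NA_real_
  a <- median(y - b * x)
  a_lo <- if (is.na(b_hi)) NA_real_ else median(y - b_hi * x)
  a_hi <- if (is.na(b_lo)) NA_real_ else median(y - b_lo * x)
  tibble::tibble(pb_slope = b, pb_intercept = a,
                 pb_slope_lo = b_lo, pb_slope_hi = b_hi,
                 pb_intercept_lo = a_lo, pb_intercept_hi = a_hi,
                 n = n)
}

#' Full concordance report between two spectra
#'
#' Matches peaks by m/z and computes the linear-fit, correlation and
#' Passing-Bablok statistics between the matched intensities.  Intended
#' for standardized spectra (a warning is issued otherwise), where slope 1
#' / intercept 0 / high correlation indicate that the two spectra share
#' one scale.
#'
#' @inheritParams match_peaks
#' @param ... Passed to [passing_bablok()].
#' @return A `spectra_concordance` object; see [tidy()] / [glance()] for
#'   tabular access.
#' @export
compare_spectra <- function(a, b, tol = 0.005, ppm = FALSE, ...) {
  sa <- as_spectrum(a); sb <- as_spectrum(b)
  if (spectrum_scale(sa) != "standardized" || spectrum_scale(sb) != "standardized") {
    warn("comparing spectra that are not both standardized; statistics reflect raw instrument scales")
  }
  pairs <- match_peaks(sa, sb, tol = tol, ppm = ppm)
  lc <- linear_concordance(pairs)
  pb <- passing_bablok(pairs, ...)
  structure(list(pairs = pairs, linear = lc, pb = pb,
                 n_matched = nrow(pairs),
                 n_unmatched_x = attr(pairs, "n_unmatched_x"),
                 n_unmatched_y = attr(pairs, "n_unmatched_y"),
                 labels = c(spectrum_label(sa), spectrum_label(sb))),
            class = "spectra_concordance")
}

#' @export
print.spectra_concordance <- function(x, ...) {
  cat(sprintf("Concordance of %d matched peak pairs (%d / %d unmatched):\n",
              x$n_matched, x$n_unmatched_x, x$n_unmatched_y))
  cat(sprintf("  OLS: slope %.4f, intercept %.4g, R^2 %.4f\n",
              x$linear$slope, x$linear$intercept, x$linear$r2))
  cat(sprintf("  Pearson r %.4f, Spearman rho %.4f\n",
              x$linear$pearson_r, x$linear$spearman_rho))
  cat(sprintf("  Passing-Bablok: slope %.4f [%.4f, %.4f], intercept %.4g [%.4g, %.4g]\n",
              x$pb$pb_slope, x$pb$pb_slope_lo, x$pb$pb_slope_hi,
              x$pb$pb_intercept, x$pb$pb_intercept_lo, x$pb$pb_intercept_hi))
  invisible(x)
}
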