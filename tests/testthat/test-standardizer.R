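# A small spectrum that standardizes quickly: 2000 peaks over 100 Th.
small_sim <- function(seed = 1) {
  simulate_plasma_spectrum(n_peaks = 2000, mz_range = c(225, 325), seed = seed)
}

test_that("window centers follow the sliding schedule", {
  # span 225-425, width 50, step 1 -> centers 250, 251, ..., 400
  s <- simulate_plasma_spectrum(n_peaks = 5000, mz_range = c(225, 425), seed = 2)
  s$mz[1] <- 225; s$mz[length(s$mz)] <- 425  # pin the exact span
  pts <- suppressMessages(compute_normalization_points(s))
  expect_equal(min(pts$center_mz), 250)
  expect_equal(max(pts$center_mz), 400)
  expect_true(all(diff(pts$center_mz) %% 1 == 0))
  all_centers <- seq(250, 400, by = 1)
  expect_true(all(pts$center_mz %in% all_centers))
  expect_equal(nrow(pts) + nrow(attr(pts, "failures")), 151)

  expect_error(
    compute_normalization_points(
      as_spectrum(data.frame(mz = seq(100, 149, length.out = 50),
                             intensity = runif(50, 1, 10)))),
    class = "kneescale_precondition_error")
})

test_that("windows in an empty m/z region are omitted, not errors", {
  s <- simulate_plasma_spectrum(n_peaks = 2400, mz_range = c(225, 345),
                                seed = 1)
  # a 60-Th hole: wider than the window, so some windows are empty
  gapped <- as_spectrum(dplyr::filter(tibble::as_tibble(s),
                                      .data$mz < 255 | .data$mz >= 315))
  pts <- suppressMessages(compute_normalization_points(gapped))
  fails <- attr(pts, "failures")
  # windows lying fully inside the gap fail occupancy and are omitted
  expect_true(all(!dplyr::between(pts$center_mz, 280, 290)))
  expect_true(any(fails$status == "occupancy" &
                    dplyr::between(fails$center_mz, 280, 290)))
  expect_gt(nrow(pts), 4)
})

test_that("normalization curve reproduces constants and smooth trends", {
  pts <- tibble::tibble(center_mz = seq(100, 200, by = 5), value = 100)
  curve <- fit_normalization_curve(pts)
  expect_equal(predict(curve, c(100, 150, 200)), rep(100, 3))
  # clamped extrapolation
  expect_equal(predict(curve, c(50, 500)), rep(100, 2))

  pts2 <- tibble::tibble(center_mz = seq(100, 200, by = 2),
                         value = 2 * seq(100, 200, by = 2))
  curve2 <- fit_normalization_curve(pts2)
  interior <- seq(110, 190, by = 5)
  expect_equal(predict(curve2, interior), 2 * interior, tolerance = 0.01)

  expect_error(fit_normalization_curve(pts2[1:3, ]),
               class = "kneescale_infeasible_error")
  expect_error(
    fit_normalization_curve(tibble::tibble(center_mz = c(1, 1, 2, 3),
                                           value = c(1, 2, 3, 4))),
    class = "kneescale_precondition_error")
})

test_that("smoothing keeps the curve within the residual bound of its points", {
  s <- small_sim(seed = 5)
  pts <- suppressMessages(compute_normalization_points(s))
  curve <- fit_normalization_curve(pts)
  at_centers <- predict(curve, pts$center_mz)
  resid_sd <- sqrt(mean((pts$value - at_centers)^2))
  expect_lte(resid_sd, 0.15 * median(pts$value))
  # curve is strictly positive over its support
  grid <- seq(curve$range[1], curve$range[2], length.out = 1000)
  expect_true(all(predict(curve, grid) > 0))
})

test_that("standardization divides by the curve and conserves peaks", {
  s <- small_sim()
  res <- suppressMessages(standardize(s))
  expect_identical(spectrum_scale(res$spectrum), "standardized")
  expect_identical(res$spectrum$mz, s$mz)
  expect_equal(nrow(res$spectrum), nrow(s))
  # definition: intensity divided by curve value at the peak m/z
  v <- predict(res$curve, s$mz)
  expect_equal(res$spectrum$intensity, s$intensity / v, tolerance = 1e-12)

  # manual composition is identical
  pts <- suppressMessages(compute_normalization_points(s))
  curve <- fit_normalization_curve(pts)
  manual <- standardize_spectrum(s, curve)
  expect_equal(res$spectrum$intensity, manual$intensity, tolerance = 1e-12)
})

test_that("standardization is invariant under uniform intensity rescaling", {
  s <- small_sim(seed = 3)
  ref <- suppressMessages(standardize(s))$spectrum
  for (alpha in c(0.1, 10)) {
    out <- suppressMessages(standardize(scale_intensities(s, alpha)))$spectrum
    expect_equal(out$intensity, ref$intensity, tolerance = 1e-9)
    expect_identical(out$mz, ref$mz)
  }
})

test_that("standardizing twice is approximately idempotent", {
  s <- small_sim(seed = 7)
  std <- suppressMessages(standardize(s))$spectrum
  pts <- suppressMessages(compute_normalization_points(std))
  # knee values of an already-standardized spectrum sit near 1
  expect_true(all(pts$value > 0.8 & pts$value < 1.2))
})

test_that("distortions varying slowly against the window are removed", {
  # full-range fingerprint: the distortion scale (sigma 200 Th, ramp over
  # 1200 Th) is well beyond the 50-Th window, the regime in which window
  # normalization can track the distortion factor
  s <- simulate_plasma_spectrum(n_peaks = 12000, mz_range = c(100, 1300),
                                seed = 1)
  std0 <- suppressMessages(standardize(s, step = 2))$spectrum
  for (kind in c("uniform", "ramp", "gaussian")) {
    d <- apply_distortion(s, kind)
    stdd <- suppressMessages(standardize(d, step = 2))$spectrum
    lc <- linear_concordance(match_peaks(std0, stdd, tol = 1e-9))
    expect_gte(lc$r2, 0.99)
    expect_true(lc$slope >= 0.95 && lc$slope <= 1.05)
  }
})

test_that("replicate noise leaves standardized spectra concordant", {
  # at instrument-repeatability noise (cv 0.1); under multiplicative noise
  # of CV c the pairwise Pearson r of matched replicates is bounded above
  # by 1/(1 + c^2) whatever the intensity law, so biological-level noise
  # (cv 0.46) caps r near 0.83 and is checked by rank correlation instead
  s <- small_sim(seed = 9)
  r1 <- suppressMessages(standardize(add_intensity_noise(s, cv = 0.1, seed = 101)))$spectrum
  r2 <- suppressMessages(standardize(add_intensity_noise(s, cv = 0.1, seed = 102)))$spectrum
  expect_gte(cor(r1$intensity, r2$intensity), 0.9)

  b1 <- suppressMessages(standardize(add_intensity_noise(s, cv = 0.46, seed = 103)))$spectrum
  b2 <- suppressMessages(standardize(add_intensity_noise(s, cv = 0.46, seed = 104)))$spectrum
  expect_gt(cor(b1$intensity, b2$intensity, method = "spearman"), 0.05)
})
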