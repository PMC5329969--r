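test_that("peak matching is tolerance-bounded, 1:1 and symmetric", {
  a <- as_spectrum(data.frame(mz = c(100, 150, 200), intensity = c(1, 2, 3)))
  b <- as_spectrum(data.frame(mz = c(100, 150, 200), intensity = c(4, 5, 6)))

  m <- match_peaks(a, b, tol = 0.01)
  expect_equal(nrow(m), 3)
  expect_equal(m$x, c(1, 2, 3)); expect_equal(m$y, c(4, 5, 6))
  expect_equal(attr(m, "n_unmatched_x"), 0)

  # shift beyond tolerance -> zero matches
  b_shift <- as_spectrum(data.frame(mz = c(100, 150, 200) + 0.1,
                                    intensity = c(4, 5, 6)))
  expect_equal(nrow(match_peaks(a, b_shift, tol = 0.05)), 0)

  # tol = 0 matches exact equality only
  b_mixed <- as_spectrum(data.frame(mz = c(100, 150.0001, 200),
                                    intensity = c(4, 5, 6)))
  expect_equal(nrow(match_peaks(a, b_mixed, tol = 0)), 2)

  # symmetry: same pairs in either direction
  set.seed(3)
  x <- simulate_plasma_spectrum(n_peaks = 300, mz_range = c(100, 200), seed = 31)
  y <- as_spectrum(data.frame(mz = x$mz + rnorm(300, 0, 0.002),
                              intensity = x$intensity))
  m_xy <- match_peaks(x, y, tol = 0.005)
  m_yx <- match_peaks(y, x, tol = 0.005)
  expect_equal(nrow(m_xy), nrow(m_yx))
  ord <- order(m_yx$mz_y)  # same pair set, keyed from either side
  expect_equal(m_xy$mz_x, m_yx$mz_y[ord])
  expect_equal(m_xy$mz_y, m_yx$mz_x[ord])
  expect_equal(sort(m_xy$dmz), sort(m_yx$dmz))
})

test_that("linear concordance matches closed-form least squares", {
  p <- tibble::tibble(x = 1:20, y = 1:20)
  lc <- linear_concordance(p)
  expect_equal(lc$slope, 1); expect_equal(lc$intercept, 0)
  expect_equal(lc$r2, 1); expect_equal(lc$pearson_r, 1)
  expect_equal(lc$spearman_rho, 1)

  lc_neg <- linear_concordance(tibble::tibble(x = 1:10, y = -(1:10)))
  expect_equal(lc_neg$pearson_r, -1); expect_equal(lc_neg$r2, 1)

  # frozen 20-pair fixture against the closed-form oracle
  set.seed(99)
  p2 <- tibble::tibble(x = runif(20, 0, 10))
  p2$y <- 3 * p2$x + rnorm(20)
  lc2 <- linear_concordance(p2)
  orc <- oracle_ols(p2$x, p2$y)
  expect_equal(lc2$slope, orc$slope, tolerance = 1e-12)
  expect_equal(lc2$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(lc2$r2, orc$r2, tolerance = 1e-12)
  expect_equal(lc2$pearson_r, orc$pearson, tolerance = 1e-12)
  expect_equal(lc2$spearman_rho, orc$spearman, tolerance = 1e-12)

  expect_error(linear_concordance(tibble::tibble(x = 1:2, y = 1:2)),
               class = "kneescale_precondition_error")
  expect_error(linear_concordance(tibble::tibble(x = rep(1, 5), y = 1:5)),
               class = "kneescale_degenerate_window_error")
})

test_that("Passing-Bablok is exact on linear data and equals the O(n^2) oracle", {
  p <- tibble::tibble(x = as.numeric(1:50), y = as.numeric(1:50))
  pb <- passing_bablok(p)
  expect_equal(pb$pb_slope, 1); expect_equal(pb$pb_intercept, 0)

  p2 <- tibble::tibble(x = as.numeric(1:50), y = 2 * (1:50) + 3)
  pb2 <- passing_bablok(p2)
  expect_equal(pb2$pb_slope, 2); expect_equal(pb2$pb_intercept, 3)

  # random pairs against the brute-force reference
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 200
    x <- runif(n, 0, 100)
    y <- 1.3 * x - 5 + rnorm(n, 0, 8)
    pbr <- passing_bablok(tibble::tibble(x = x, y = y))
    orc <- oracle_passing_bablok(x, y)
    expect_equal(pbr$pb_slope, orc$slope, tolerance = 1e-12)
    expect_equal(pbr$pb_intercept, orc$intercept, tolerance = 1e-12)
    expect_true(pbr$pb_slope_lo < pbr$pb_slope & pbr$pb_slope < pbr$pb_slope_hi)
  }

  # swap consistency on exact linear data: slope -> 1/slope
  pswap <- passing_bablok(tibble::tibble(x = p2$y, y = p2$x))
  expect_equal(pswap$pb_slope, 1 / pb2$pb_slope, tolerance = 1e-12)

  expect_error(passing_bablok(tibble::tibble(x = 1:5, y = 1:5)),
               class = "kneescale_precondition_error")
  expect_error(passing_bablok(tibble::tibble(x = rep(1, 12), y = 1:12)),
               class = "kneescale_degenerate_window_error")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  p <- tibble::tibble(x = runif(30, 1, 10), y = runif(30, 1, 10))
  base <- linear_concordance(p)$spearman_rho
  expect_equal(linear_concordance(tibble::tibble(x = exp(p$x), y = p$y^3))$spearman_rho,
               base)
  expect_equal(linear_concordance(tibble::tibble(x = log(p$x), y = 10 * p$y))$spearman_rho,
               base)
})

test_that("compare_spectra composes the full report", {
  s <- simulate_plasma_spectrum(n_peaks = 400, mz_range = c(100, 250), seed = 12)
  std <- suppressMessages(standardize(s))$spectrum

  self <- compare_spectra(std, std, tol = 0)
  expect_equal(self$pb$pb_slope, 1)
  expect_equal(self$pb$pb_intercept, 0)
  expect_equal(self$linear$spearman_rho, 1)
  expect_equal(self$n_matched, nrow(std))

  g <- glance(self)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$slope, 1)
  td <- tidy(self)
  expect_true(all(c("pb_slope", "spearman_rho") %in% td$term))

  # two standardized noise replicates stay concordant
  r1 <- suppressMessages(standardize(add_intensity_noise(s, seed = 1)))$spectrum
  r2 <- suppressMessages(standardize(add_intensity_noise(s, seed = 2)))$spectrum
  cc <- compare_spectra(r1, r2, tol = 0)
  expect_true(all(is.finite(unlist(glance(cc)))))
  expect_gt(cc$linear$spearman_rho, 0)

  # raw inputs warn
  expect_warning(compare_spectra(s, s, tol = 0), "standardized")
})
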