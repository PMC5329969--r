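# Independent reference implementations used to cross-check the package's
# estimators.  They deliberately avoid the production code paths: the power
# fit is a profiled grid search (for fixed b the model is linear in a and c),
# the knee a dense-grid curvature argmax, and Passing-Bablok a plain O(n^2)
# double loop.

# Profiled least squares: grid over the exponent b, exact linear solve for
# (a, c) at each b (non-negativity enforced by clamping + refit), then local
# polish of b by golden-section. Returns the parameters and the objective.
oracle_power_fit <- function(y, b_grid = seq(-5, -0.01, by = 0.01)) {
  x <- seq_along(y)
  sse_at_b <- function(b) {
    f <- x^b
    X <- cbind(f, 1)
    ac <- solve(crossprod(X), crossprod(X, y))
    a <- ac[1]; c0 <- ac[2]
    if (a <= 0) { a <- 1e-12 }
    if (c0 < 0) { # refit with c = 0
      a <- sum(f * y) / sum(f * f); c0 <- 0
      if (a <= 0) a <- 1e-12
    }
    list(a = a, c = c0, sse = sum((y - a * f - c0)^2))
  }
  sses <- vapply(b_grid, function(b) sse_at_b(b)$sse, numeric(1))
  i <- which.min(sses)
  lo <- b_grid[max(i - 1, 1)]; hi <- b_grid[min(i + 1, length(b_grid))]
  opt <- stats::optimize(function(b) sse_at_b(b)$sse, lower = lo, upper = hi,
                         tol = 1e-10)
  best <- sse_at_b(opt$minimum)
  list(a = best$a, b = opt$minimum, c = best$c, sse = best$sse)
}

oracle_power_sse <- function(y, a, b, c0) {
  x <- seq_along(y)
  sum((y - (a * x^b + c0))^2)
}

# Dense-grid argmax of the curvature of the axis-normalized curve
# y = a x^b + c over ranks [1, n]; returns the knee rank.
oracle_knee_rank <- function(a, b, c0, n, grid_n = 1e5) {
  t <- seq(1 / n, 1, length.out = grid_n)
  x <- n * t
  yrange <- a * (1 - n^b)
  g1 <- a * b * x^(b - 1) * n / yrange
  g2 <- a * b * (b - 1) * x^(b - 2) * n^2 / yrange
  kappa <- abs(g2) / (1 + g1^2)^1.5
  n * t[which.max(kappa)]
}

# Naive O(n^2) Passing-Bablok with explicit loops.
oracle_passing_bablok <- function(x, y) {
  n <- length(x)
  S <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- dy / dx
      if (s == -1) next
      S <- c(S, s)
    }
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  b <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else (S[N / 2 + K] + S[N / 2 + K + 1]) / 2
  a <- stats::median(y - b * x)
  list(slope = b, intercept = a)
}

# Closed-form simple linear regression and correlations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  pearson <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  list(slope = slope, intercept = intercept, r2 = r2, pearson = pearson,
       spearman = stats::cor(rank(x), rank(y)))
}
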