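# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, dense linear algebra, closed forms.

# high-resolution left-Riemann integral of f on [0, T]
riemann_integral <- function(f, T, n = 1e6) {
  h <- T / n
  sum(f((0:(n - 1)) * h)) * h
}

# brute-force cumulative trapezoid (loop, no cumsum)
trapz_loop <- function(y, h) {
  v <- numeric(length(y))
  for (i in 2:length(y)) v[i] <- v[i - 1] + (y[i - 1] + y[i]) * h / 2
  v
}

# brute-force argmax (0-based, earliest tie) of the two-point drift-corrected
# integrated volume of `values` between 0-based indices a and b
brute_volume_argmax <- function(values, fs, a, b, drift_correct = TRUE) {
  y <- values[(a + 1):(b + 1)]
  v <- trapz_loop(y, 1 / fs)
  if (drift_correct) {
    m <- length(v)
    v <- v - v[m] * (0:(m - 1)) / (m - 1)
  }
  a + which.max(v) - 1
}

# centered finite-difference second-derivative argmax within a segment
# (0-based indices), the noise-free inflection oracle
fd_inflection_argmax <- function(values, segment, minimum = FALSE) {
  y <- values[(segment[1] + 1):(segment[2] + 1)]
  d2 <- c(NA, diff(diff(y)), NA)
  if (minimum) d2 <- -d2
  segment[1] + which.max(d2) - 1
}

# dense quadratic-program smoothing spline in the penalized convention:
# minimize p * ||y - a||^2 + (1 - p) * g' R g  s.t.  Q'a = R g
# solved by a = (I + lambda K)^{-1} y with K = Q R^{-1} Q'
qp_smoothing_spline <- function(y, h, p) {
  n <- length(y)
  m <- n - 2
  Q <- matrix(0, n, m)
  for (j in 1:m) {
    Q[j, j] <- 1 / h; Q[j + 1, j] <- -2 / h; Q[j + 2, j] <- 1 / h
  }
  R <- matrix(0, m, m)
  for (j in 1:m) {
    R[j, j] <- 2 * h / 3
    if (j < m) { R[j, j + 1] <- h / 6; R[j + 1, j] <- h / 6 }
  }
  K <- Q %*% solve(R) %*% t(Q)
  lambda <- (1 - p) / p
  a <- solve(diag(n) + lambda * K, y)
  g <- solve(R, t(Q) %*% a)
  list(fitted = as.numeric(a), d2 = c(0, as.numeric(g), 0))
}

# closed-form OLS via normal equations (no lm)
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(resid^2) / sst, sse = sum(resid^2))
}

# known-mean sample autocovariance at lag k (FGN has mean zero by
# construction; using the true mean avoids the large long-memory bias of the
# mean-subtracted estimator)
acov_known_mean <- function(x, k) {
  n <- length(x)
  mean(x[1:(n - k)] * x[(1 + k):n])
}

# small clean synthetic breath signal shared by detector tests
clean_case <- function(bpm = 12, fs = 250, n_breaths = 6, ...) {
  clean_breath_signal(
    synthetic_spec(f1_bpm = bpm, fs = fs, noise_level = 0, ...),
    n_breaths
  )
}
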