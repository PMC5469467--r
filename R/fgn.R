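#' Theoretical autocovariance of fractional Gaussian noise
#'
#' gamma(k) = (sd^2 / 2) * (|k+1|^(2H) - 2 |k|^(2H) + |k-1|^(2H)). For
#' H = 0.5 this is zero at every nonzero lag (white noise); for H > 0.5 the
#' noise is persistent with slowly decaying positive correlations.
#'
#' @param k Integer lag(s), >= 0.
#' @param hurst Hurst exponent in (0, 1).
#' @param sd Marginal standard deviation.
#' @return Autocovariance at lag(s) `k`.
#' @export
fgn_autocovariance <- function(k, hurst, sd = 1) {
  h2 <- 2 * hurst
  (sd^2 / 2) * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Simulate fractional Gaussian noise (Davies-Harte)
#'
#' Generates a stationary, zero-mean Gaussian sequence with the exact
#' fractional-Gaussian-noise autocovariance via circulant embedding: the
#' covariance of lags 0..n-1 is reflected into a circulant row of length
#' 2(n-1) (padded to the next power of two), its eigenvalues obtained by FFT,
#' checked for non-negativity, and the sequence synthesized from complex
#' Gaussian spectral weights.
#'
#' Used here to model the breath-by-breath wander of the flow baseline
#' (Hurst exponent 0.9, SD 0.1 by default in the synthetic model).
#'
#' @param n Number of samples (>= 2).
#' @param hurst Hurst exponent in (0, 1). 0.5 gives white noise.
#' @param sd Marginal standard deviation.
#' @param seed Optional integer seed; when supplied the stream is local (the
#'   caller's RNG state is untouched). When `NULL`, draws from the current
#'   RNG stream.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- fractional_gaussian_noise(1e4, hurst = 0.9, sd = 0.1, seed = 1)
#' sd(x)
fractional_gaussian_noise <- function(n, hurst, sd = 1, seed = NULL) {
  if (!(hurst > 0 && hurst < 1)) {
    stop("config error: `hurst` must be in (0, 1)", call. = FALSE)
  }
  if (n < 2) stop("config error: `n` must be >= 2", call. = FALSE)
  if (!is.null(seed)) {
    return(with_local_seed(seed, fractional_gaussian_noise(n, hurst, sd)))
  }
  # circulant embedding of size m = 2 * next power of two >= n - 1
  m <- 2L * 2L^ceiling(log2(max(n - 1L, 2L)))
  acov <- fgn_autocovariance(0:(m / 2L), hurst, sd)
  row1 <- c(acov, rev(acov[2:(m / 2L)]))
  ev <- Re(stats::fft(row1))
  tol <- -1e-8 * max(ev)
  if (any(ev < tol)) {
    stop(paste0(
      "numerical error: circulant embedding has negative eigenvalues; ",
      "increase the embedding size"
    ), call. = FALSE)
  }
  ev[ev < 0] <- 0
  half <- m / 2L
  # complex spectral weights with the symmetry that makes the result real
  z <- complex(length.out = m)
  z[1L] <- sqrt(ev[1L]) * stats::rnorm(1)
  z[half + 1L] <- sqrt(ev[half + 1L]) * stats::rnorm(1)
  a <- stats::rnorm(half - 1L)
  b <- stats::rnorm(half - 1L)
  z[2:half] <- sqrt(ev[2:half] / 2) * complex(real = a, imaginary = b)
  z[(half + 2L):m] <- Conj(rev(z[2:half]))
  x <- Re(stats::fft(z)) / sqrt(m)
  x[seq_len(n)]
}

# run `expr` under a temporary RNG seed, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
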