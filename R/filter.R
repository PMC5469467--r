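#' Design a digital Butterworth low-pass filter
#'
#' Standard bilinear-transform design: analog Butterworth prototype poles,
#' frequency prewarping, bilinear mapping to the z-plane, and unit gain at
#' DC. Used internally for the 2 Hz zero-phase low-pass that guides peak and
#' valley detection; exported because filter design is occasionally useful
#' on its own.
#'
#' @param cutoff_hz Cut-off frequency in Hz (0 < cutoff < fs/2).
#' @param fs Sampling frequency in Hz.
#' @param order Filter order (default 4).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(cutoff_hz, fs, order = 4L) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("config error: cutoff must lie strictly between 0 and fs/2", call. = FALSE)
  }
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p <- complex(modulus = 1, argument = theta)
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  p <- p * warped
  # bilinear transform: z = (2 fs + s) / (2 fs - s)
  pz <- (2 * fs + p) / (2 * fs - p)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  # normalize to unit gain at z = 1 (DC)
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# monic polynomial coefficients from roots, highest order first
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (root in r) coef <- c(coef, 0) - c(0, coef * root)
  coef
}

# direct-form IIR filter: a[1] y[t] = sum b x[t-j] - sum a[-1] y[t-j].
# Both stages start from the steady state for a constant input at x[1]
# (unit-DC-gain filter), so a constant signal passes through exactly and
# start-up transients are suppressed beyond what the edge padding handles.
iir_filter <- function(b, a, x) {
  b <- b / a[1L]
  a <- a / a[1L]
  z <- stats::filter(c(rep(x[1L], length(b) - 1L), x), b,
                     method = "convolution", sides = 1)
  z <- as.numeric(z)[length(b):(length(b) - 1L + length(x))]
  if (length(a) > 1L) {
    z <- as.numeric(stats::filter(z, -a[-1L], method = "recursive",
                                  init = rep(x[1L], length(a) - 1L)))
  }
  z
}

#' Zero-phase low-pass filtering
#'
#' Applies a Butterworth low-pass forward and backward so the net filter has
#' zero phase and does not bias the timing of peaks or onsets. Edge
#' transients are handled by odd (point-reflected) extension of the signal at
#' both ends before filtering.
#'
#' @param x Numeric vector.
#' @param cutoff_hz Cut-off frequency (Hz).
#' @param fs Sampling frequency (Hz).
#' @param order Butterworth order (default 4; each pass, so 8 poles net).
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass_zerophase <- function(x, cutoff_hz, fs, order = 4L) {
  coefs <- butter_lowpass(cutoff_hz, fs, order)
  n <- length(x)
  pad <- min(n - 1L, max(50L, as.integer(3 * fs / cutoff_hz)))
  head_ext <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(coefs$b, coefs$a, xe)
  y <- rev(iir_filter(coefs$b, coefs$a, rev(y)))
  y[(pad + 1L):(pad + n)]
}
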