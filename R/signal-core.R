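#' Construct a uniformly sampled physiological signal
#'
#' A `sampled_signal` holds one channel of a respiratory recording: a numeric
#' vector of samples, its sampling frequency, and the kind of quantity it
#' measures. Sample `i` (0-based) is taken at time `t0 + i/fs` seconds.
#'
#' @param values Numeric vector of samples. Units are L/s for `"flow"`,
#'   cmH2O for `"pressure"`, L for `"volume"`.
#' @param fs Sampling frequency in Hz (> 0).
#' @param kind One of `"flow"`, `"pressure"`, `"volume"`.
#' @param t0 Start time of the first sample in seconds (default 0).
#'
#' @return An object of class `sampled_signal` (a list with elements
#'   `values`, `fs`, `kind`, `t0`).
#' @seealso [validate_signal()], [idx_to_seconds()], [cumulative_volume()]
#' @export
#' @examples
#' sig <- sampled_signal(sin(seq(0, 2 * pi, length.out = 500)), fs = 250)
#' sig
sampled_signal <- function(values, fs, kind = c("flow", "pressure", "volume"),
                           t0 = 0) {
  kind <- match.arg(kind)
  x <- structure(
    list(values = as.numeric(values), fs = fs, kind = kind, t0 = t0),
    class = "sampled_signal"
  )
  validate_signal(x)
}

#' Validate a sampled signal
#'
#' Checks the `sampled_signal` invariants: positive sampling frequency, at
#' least two samples, and no non-finite values. Returns the signal unchanged
#' when valid; otherwise throws an error identifying the problem (including
#' the first offending sample index for non-finite data).
#'
#' @param signal A [sampled_signal()].
#' @return `signal`, invisibly unchanged.
#' @export
validate_signal <- function(signal) {
  if (!inherits(signal, "sampled_signal")) {
    stop("`signal` must be a sampled_signal object", call. = FALSE)
  }
  if (!is.numeric(signal$fs) || length(signal$fs) != 1L ||
      !is.finite(signal$fs) || signal$fs <= 0) {
    stop("config error: `fs` must be a single positive number", call. = FALSE)
  }
  if (length(signal$values) < 2L) {
    stop("data error: signal must contain at least 2 samples", call. = FALSE)
  }
  bad <- which(!is.finite(signal$values))
  if (length(bad) > 0L) {
    stop(sprintf(
      "data error: non-finite value at sample index %d (0-based)", bad[1L] - 1L
    ), call. = FALSE)
  }
  if (!is.numeric(signal$t0) || length(signal$t0) != 1L || !is.finite(signal$t0)) {
    stop("config error: `t0` must be a single finite number", call. = FALSE)
  }
  signal
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<sampled_signal> kind=%s  n=%d  fs=%g Hz  duration=%.3f s  t0=%g s\n",
    x$kind, length(x$values), x$fs, (length(x$values) - 1L) / x$fs, x$t0
  ))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Convert a sample index to seconds
#'
#' @param idx 0-based sample index (vectorized).
#' @param signal A [sampled_signal()].
#' @return Time in seconds: `t0 + idx / fs`.
#' @export
#' @examples
#' sig <- sampled_signal(numeric(500), fs = 250)
#' idx_to_seconds(c(0, 250), sig) # 0 and 1 second
idx_to_seconds <- function(idx, signal) {
  n <- length(signal$values)
  if (any(idx < 0 | idx > n - 1L)) {
    stop("bounds error: index outside signal range", call. = FALSE)
  }
  signal$t0 + idx / signal$fs
}

#' Convert a time in seconds to the nearest sample index
#'
#' @param t Time(s) in seconds.
#' @param signal A [sampled_signal()].
#' @return 0-based sample index, `round((t - t0) * fs)`.
#' @export
seconds_to_idx <- function(t, signal) {
  as.integer(round((t - signal$t0) * signal$fs))
}

#' Cumulative volume from a flow signal
#'
#' Trapezoidal cumulative integral of flow over a sample range, re-zeroed at
#' the start of the range, so the value at `start_idx` is 0 L. This is the
#' raw (uncorrected) integrated volume; per-breath drift correction is applied
#' where breaths are delimited (see [detect_expiratory_onsets()]).
#'
#' @param flow A [sampled_signal()] with `kind = "flow"`.
#' @param start_idx,end_idx 0-based sample indices, `start_idx < end_idx`.
#' @return Numeric vector of length `end_idx - start_idx + 1`, volume in L.
#' @export
#' @examples
#' fl <- sampled_signal(rep(0.5, 501), fs = 250)
#' v <- cumulative_volume(fl, 0, 500)
#' v[length(v)] # 1 L after 2 s at 0.5 L/s
cumulative_volume <- function(flow, start_idx, end_idx) {
  if (flow$kind != "flow") {
    stop("config error: cumulative_volume requires a flow signal", call. = FALSE)
  }
  n <- length(flow$values)
  if (start_idx < 0 || end_idx > n - 1L || start_idx >= end_idx) {
    stop("bounds error: require 0 <= start_idx < end_idx <= n-1", call. = FALSE)
  }
  y <- flow$values[(start_idx + 1L):(end_idx + 1L)]
  cumtrapz(y, 1 / flow$fs)
}

# cumulative trapezoid with uniform spacing h; first element 0
cumtrapz <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-n] + y[-1L]) * (h / 2)))
}

#' Construct a breath annotation
#'
#' An ordered set of breaths, each an (inspiratory onset, expiratory onset)
#' pair of 0-based sample indices into the original signal. Inspiratory
#' onsets must be strictly increasing and each expiratory onset must follow
#' its inspiratory onset. The expiration of breath `k` ends at the
#' inspiratory onset of breath `k + 1`, so no constraint ties
#' `exp_onset_idx[k]` to `insp_onset_idx[k + 1]` beyond the per-breath order.
#'
#' @param insp_onset_idx Integer vector of 0-based inspiratory onset indices.
#' @param exp_onset_idx Integer vector of 0-based expiratory onset indices,
#'   same length.
#' @param fs Sampling frequency (Hz) of the annotated signal.
#' @param n_samples Optional signal length for bounds checking.
#' @return An object of class `breath_annotation`.
#' @export
breath_annotation <- function(insp_onset_idx, exp_onset_idx, fs,
                              n_samples = NULL) {
  insp <- as.integer(insp_onset_idx)
  expo <- as.integer(exp_onset_idx)
  if (length(insp) != length(expo)) {
    stop("consistency error: onset vectors must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("config error: `fs` must be a single positive number", call. = FALSE)
  }
  if (length(insp) > 0L) {
    if (any(insp >= expo)) {
      stop("annotation error: each inspiratory onset must precede its expiratory onset",
           call. = FALSE)
    }
    if (length(insp) > 1L && any(diff(insp) <= 0L)) {
      stop("annotation error: inspiratory onsets must be strictly increasing",
           call. = FALSE)
    }
    if (any(insp < 0L)) {
      stop("bounds error: negative onset index", call. = FALSE)
    }
    if (!is.null(n_samples) && any(expo > n_samples - 1L)) {
      stop("bounds error: onset index beyond signal end", call. = FALSE)
    }
  }
  structure(
    list(insp_onset_idx = insp, exp_onset_idx = expo, fs = fs),
    class = "breath_annotation"
  )
}

#' @export
print.breath_annotation <- function(x, ...) {
  cat(sprintf("<breath_annotation> %d breaths  fs=%g Hz\n",
              length(x$insp_onset_idx), x$fs))
  if (length(x$insp_onset_idx) > 0L) {
    cat(sprintf("  first inspiratory onset at %.3f s, last at %.3f s\n",
                x$insp_onset_idx[1L] / x$fs,
                x$insp_onset_idx[length(x$insp_onset_idx)] / x$fs))
  }
  invisible(x)
}

#' @export
length.breath_annotation <- function(x) length(x$insp_onset_idx)

#' @export
as.data.frame.breath_annotation <- function(x, ...) {
  data.frame(
    breath = seq_along(x$insp_onset_idx),
    insp_onset_idx = x$insp_onset_idx,
    exp_onset_idx = x$exp_onset_idx,
    insp_onset_s = x$insp_onset_idx / x$fs,
    exp_onset_s = x$exp_onset_idx / x$fs
  )
}
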