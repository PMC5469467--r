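#' Detection configuration
#'
#' Tunable parameters of the breath detector. Defaults follow the published
#' procedure: a 2 Hz zero-phase low-pass guides peak/valley detection, peaks
#' must be at least one breath duration (1 s) apart, and the smoothing spline
#' uses `sp = 0.95` in the penalized convention of [smoothing_spline()] with
#' x in seconds.
#'
#' @param cutoff_hz Low-pass cut-off in Hz (default 2).
#' @param min_breath_s Minimum breath duration, used as the peak-separation
#'   threshold in seconds (default 1).
#' @param sp Smoothing parameter in (0, 1] (default 0.95).
#' @param signal_kind `"flow"` (inspiration = rising limb, second-derivative
#'   maximum) or `"pepi"` (epiglottic pressure: falling limb, minimum).
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   filtered signal's interquartile range (default 0.05); suppresses
#'   micro-oscillations in noisy recordings.
#' @param min_rise_frac Minimum excursion of a candidate breath limb
#'   (filtered peak minus valley, or valley minus peak in pepi mode) as a
#'   fraction of the median excursion over the record (default 0.1).
#'   Sub-breath baseline wiggles that survive peak detection during long
#'   expirations are an order of magnitude smaller than real breaths and are
#'   rejected here.
#' @param drift_correct Apply the per-breath two-point drift correction to
#'   the integrated volume before locating expiratory onsets (default TRUE).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(cutoff_hz = 2, min_breath_s = 1, sp = 0.95,
                             signal_kind = c("flow", "pepi"),
                             min_prominence_frac = 0.05,
                             min_rise_frac = 0.1,
                             drift_correct = TRUE) {
  signal_kind <- match.arg(signal_kind)
  if (!(sp > 0 && sp <= 1)) stop("config error: `sp` must be in (0, 1]", call. = FALSE)
  if (min_breath_s <= 0) stop("config error: `min_breath_s` must be > 0", call. = FALSE)
  if (cutoff_hz <= 0) stop("config error: `cutoff_hz` must be > 0", call. = FALSE)
  structure(
    list(cutoff_hz = cutoff_hz, min_breath_s = min_breath_s, sp = sp,
         signal_kind = signal_kind, min_prominence_frac = min_prominence_frac,
         min_rise_frac = min_rise_frac, drift_correct = drift_correct),
    class = "detection_config"
  )
}

#' Find interleaved peaks and valleys of the filtered signal
#'
#' Applies the zero-phase low-pass at `cutoff_hz`, finds local maxima at
#' least `min_breath_s` apart (taller peak wins within the exclusion window)
#' with a minimum prominence of `min_prominence_frac` of the filtered
#' signal's interquartile range, finds valleys the same way on the negated
#' filtered signal, and reconciles the two lists into strict alternation
#' (between two same-type extrema the more extreme one is kept).
#'
#' @param signal A [sampled_signal()].
#' @param config A [detection_config()].
#' @return List with integer vectors `peaks` and `valleys` (0-based indices)
#'   and the `filtered` signal values.
#' @export
find_extrema <- function(signal, config = detection_config()) {
  validate_signal(signal)
  fs <- signal$fs
  if (config$cutoff_hz >= fs / 2) {
    stop("config error: low-pass cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  xf <- lowpass_zerophase(signal$values, config$cutoff_hz, fs)
  min_sep <- as.integer(round(config$min_breath_s * fs))
  # absolute floor guards against numerical ripple on (near-)constant input
  min_prom <- max(config$min_prominence_frac * stats::IQR(xf),
                  1e-12 * max(abs(xf), 1))
  peaks <- find_peaks(xf, min_sep, min_prom)
  valleys <- find_peaks(-xf, min_sep, min_prom)
  rec <- alternate_extrema(peaks, valleys, xf)
  list(peaks = rec$peaks, valleys = rec$valleys, filtered = xf)
}

# Local maxima of x with minimum separation and minimum prominence.
# Returns 0-based indices. Plateaus take their first sample.
find_peaks <- function(x, min_sep, min_prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x)) # length n - 1
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  nzcount <- cumsum(s != 0)
  nzval <- s[nz]
  # candidate falls: s[i] == -1 with the most recent nonzero sign before i == +1
  prev_count <- c(0L, nzcount[-length(nzcount)])
  prev_sign <- ifelse(prev_count > 0L, nzval[pmax(prev_count, 1L)], 0)
  cand_fall <- which(s == -1 & prev_sign == 1)
  if (length(cand_fall) == 0L) return(integer(0))
  # first sample of the plateau: one past the position of the last rise
  rise_pos <- nz[prev_count[cand_fall]]
  cand <- sort(unique(rise_pos + 1L)) # 1-based sample indices
  # enforce separation: taller peaks claim their exclusion window first
  if (length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    excluded <- logical(n)
    taken <- integer(0)
    for (i in ord) {
      if (!excluded[i]) {
        taken <- c(taken, i)
        excluded[max(1L, i - min_sep + 1L):min(n, i + min_sep - 1L)] <- TRUE
      }
    }
    cand <- sort(taken)
  }
  if (min_prom > 0 && length(cand) > 0L) {
    cand <- cand[peak_prominence(x, cand) >= min_prom]
  }
  cand - 1L # 0-based
}

# prominence of the (separation-thinned) peaks: height above the higher of
# the two deepest dips separating the peak from its neighboring peaks (the
# record edges for the outermost peaks); O(n) in total
peak_prominence <- function(x, cand) {
  k <- length(cand)
  bounds <- c(1L, cand, length(x))
  # deepest dip between consecutive peaks (and from edges to the outer peaks)
  dips <- vapply(seq_len(k + 1L), function(j) {
    min(x[bounds[j]:bounds[j + 1L]])
  }, numeric(1))
  x[cand] - pmax(dips[seq_len(k)], dips[2:(k + 1L)])
}

# enforce strict peak/valley alternation: between two same-type extrema keep
# the more extreme one
alternate_extrema <- function(peaks, valleys, xf) {
  if (length(peaks) == 0L || length(valleys) == 0L) {
    return(list(peaks = peaks, valleys = valleys))
  }
  ev <- rbind(
    data.frame(idx = peaks, type = 1L),
    data.frame(idx = valleys, type = -1L)
  )
  ev <- ev[order(ev$idx), ]
  keep <- rep(TRUE, nrow(ev))
  i <- 1L
  while (i < nrow(ev)) {
    j <- i + 1L
    while (j <= nrow(ev) && !keep[j]) j <- j + 1L
    if (j > nrow(ev)) break
    if (ev$type[i] == ev$type[j]) {
      vi <- xf[ev$idx[i] + 1L] * ev$type[i]
      vj <- xf[ev$idx[j] + 1L] * ev$type[j]
      if (vi >= vj) keep[j] <- FALSE else { keep[i] <- FALSE; i <- j }
    } else {
      i <- j
    }
  }
  ev <- ev[keep, ]
  list(peaks = ev$idx[ev$type == 1L], valleys = ev$idx[ev$type == -1L])
}

#' Extract per-breath onset segments
#'
#' In flow mode each segment runs from a valley to the next peak (the rising
#' limb that contains the inspiratory kink); in pepi mode from a peak to the
#' next valley (the falling limb). Segments are defined on the raw,
#' unfiltered samples; the filter only guides extremum placement. Segments
#' shorter than 4 samples (too short for a cubic spline) are dropped and
#' counted.
#'
#' @param signal A [sampled_signal()] (raw).
#' @param peaks,valleys 0-based extremum indices from [find_extrema()].
#' @param config A [detection_config()].
#' @return List with `segments` (list of `c(start_idx, end_idx)` 0-based
#'   pairs) and `n_skipped`.
#' @export
extract_onset_segments <- function(signal, peaks, valleys,
                                   config = detection_config()) {
  if (config$signal_kind == "flow") {
    starts <- valleys; ends <- peaks
  } else {
    starts <- peaks; ends <- valleys
  }
  segments <- list()
  n_skipped <- 0L
  for (s in starts) {
    e <- ends[ends > s]
    if (length(e) == 0L) next # truncated record: unpaired start
    e <- e[1L]
    if (e - s + 1L < 4L) { n_skipped <- n_skipped + 1L; next }
    segments[[length(segments) + 1L]] <- c(s, e)
  }
  list(segments = segments, n_skipped = n_skipped)
}

#' Locate the inspiratory-onset inflection point within one segment
#'
#' Fits the penalized cubic smoothing spline ([smoothing_spline()], x in
#' seconds, smoothing parameter `config$sp`) to the raw samples of the
#' segment and returns the sample index where the fitted second derivative
#' attains its maximum (flow) or minimum (pepi); ties take the earliest
#' index. Candidates within 2 samples of a segment boundary are treated as
#' spurious edge extrema: the segment is widened once by 25% on each side
#' (clipped to the record) and refitted; the refit result is accepted either
#' way.
#'
#' @param signal A [sampled_signal()] (raw).
#' @param segment `c(start_idx, end_idx)` 0-based pair.
#' @param config A [detection_config()].
#' @return 0-based onset index within the original signal, or `NA_integer_`
#'   for a degenerate (constant) segment.
#' @export
locate_inflection <- function(signal, segment, config = detection_config()) {
  res <- inflection_once(signal, segment, config)
  if (is.na(res$idx)) return(NA_integer_)
  n_seg <- segment[2L] - segment[1L] + 1L
  near_edge <- res$idx - segment[1L] < 2L || segment[2L] - res$idx < 2L
  if (near_edge) {
    pad <- max(1L, as.integer(round(0.25 * n_seg)))
    wide <- c(max(0L, segment[1L] - pad),
              min(length(signal$values) - 1L, segment[2L] + pad))
    res <- inflection_once(signal, wide, config)
  }
  as.integer(res$idx)
}

inflection_once <- function(signal, segment, config) {
  y <- signal$values[(segment[1L] + 1L):(segment[2L] + 1L)]
  if (max(y) - min(y) < .Machine$double.eps * 100) {
    return(list(idx = NA_integer_)) # degenerate constant segment
  }
  fit <- smoothing_spline(y, h = 1 / signal$fs, p = config$sp)
  d2 <- if (config$signal_kind == "flow") fit$d2 else -fit$d2
  list(idx = segment[1L] + which.max(d2) - 1L)
}

#' Detect inspiratory onsets
#'
#' The three-step pipeline: zero-phase low-pass and peak/valley detection,
#' per-breath segment extraction, and smoothing-spline second-derivative
#' extremum location on the raw samples of each segment. Returns strictly
#' increasing onset indices at least `min_breath_s` apart (where candidates
#' violate the spacing, the earlier onset wins).
#'
#' @param signal A [sampled_signal()].
#' @param config A [detection_config()].
#' @return Integer vector of 0-based onset indices (possibly empty).
#' @export
detect_inspiratory_onsets <- function(signal, config = detection_config()) {
  validate_signal(signal)
  ext <- find_extrema(signal, config)
  segs <- extract_onset_segments(signal, ext$peaks, ext$valleys, config)
  segments <- segs$segments
  if (length(segments) > 1L && config$min_rise_frac > 0) {
    rises <- vapply(segments, function(seg) {
      r <- ext$filtered[seg[2L] + 1L] - ext$filtered[seg[1L] + 1L]
      if (config$signal_kind == "pepi") -r else r
    }, numeric(1))
    segments <- segments[rises >= config$min_rise_frac * stats::median(rises)]
  }
  onsets <- vapply(segments, function(seg) {
    locate_inflection(signal, seg, config)
  }, integer(1))
  onsets <- sort(onsets[!is.na(onsets)])
  enforce_min_spacing(onsets, config$min_breath_s * signal$fs)
}

enforce_min_spacing <- function(idx, min_sep) {
  if (length(idx) < 2L) return(idx)
  keep <- idx[1L]
  for (i in idx[-1L]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
  }
  keep
}

# argmax index (0-based, earliest tie) of the drift-corrected cumulative
# volume of `signal` between onsets a and b (two-point correction: the
# straight line through the volume endpoints is subtracted)
volume_peak_index <- function(signal, a, b, drift_correct = TRUE) {
  v <- cumulative_volume(signal, a, b)
  if (drift_correct) {
    m <- length(v)
    v <- v - v[m] * (seq_len(m) - 1) / (m - 1)
  }
  a + which.max(v) - 1L
}

#' Detect expiratory onsets
#'
#' Flow mode: for each pair of adjacent inspiratory onsets, the expiratory
#' onset is the maximum of the drift-corrected integrated volume (flow
#' integrated from the first onset, with the straight line through the two
#' endpoint volumes subtracted so baseline drift and net model volume cannot
#' push the maximum to the breath boundary); ties take the earliest sample.
#' The last breath integrates to the end of the record and is flagged as the
#' tail.
#'
#' Pepi mode: the straight line through the pressure values at the two
#' adjacent inspiratory onsets is intersected with the pressure waveform; the
#' expiratory onset is the first sample strictly after the breath's pressure
#' nadir at which the waveform returns up to the line. For the last breath
#' the line is extended with the mean slope of the preceding breaths. Breaths
#' with no crossing are flagged unresolved (`NA`).
#'
#' @param signal A [sampled_signal()] (flow in L/s, or epiglottic pressure in
#'   cmH2O for `signal_kind = "pepi"`).
#' @param insp_onsets Integer vector (0-based) of >= 2 inspiratory onsets.
#' @param config A [detection_config()].
#' @return Integer vector, one expiratory onset per inspiratory onset
#'   (`NA_integer_` where unresolved).
#' @export
detect_expiratory_onsets <- function(signal, insp_onsets,
                                     config = detection_config()) {
  if (length(insp_onsets) < 2L) {
    stop("data error: need at least 2 inspiratory onsets", call. = FALSE)
  }
  n <- length(signal$values)
  k <- length(insp_onsets)
  out <- rep(NA_integer_, k)
  if (config$signal_kind == "flow") {
    ends <- c(insp_onsets[-1L], n - 1L)
    for (i in seq_len(k)) {
      out[i] <- volume_peak_index(signal, insp_onsets[i], ends[i],
                                  config$drift_correct)
    }
  } else {
    x <- signal$values
    slopes <- numeric(0)
    for (i in seq_len(k)) {
      a <- insp_onsets[i]
      if (i < k) {
        b <- insp_onsets[i + 1L]
        slope <- (x[b + 1L] - x[a + 1L]) / (b - a)
        slopes <- c(slopes, slope)
      } else {
        if (length(slopes) == 0L) next
        slope <- mean(slopes)
        b <- n - 1L
      }
      if (b - a < 2L) next
      seg <- a:b
      line <- x[a + 1L] + slope * (seg - a)
      resid <- x[seg + 1L] - line
      nadir <- a + which.min(resid) - 1L
      if (nadir >= b) next
      after <- (nadir + 1L):b
      cross <- after[x[after + 1L] >= line[after - a + 1L]]
      if (length(cross) > 0L) out[i] <- cross[1L]
    }
  }
  out
}

#' Detect breaths end to end
#'
#' Runs inspiratory-onset detection followed by expiratory-onset detection
#' and assembles a [breath_annotation()]. Breaths whose expiratory onset is
#' unresolved, or that would violate the annotation invariants, are dropped
#' and counted in the attached run report.
#'
#' @param signal A [sampled_signal()].
#' @param config A [detection_config()].
#' @return A [breath_annotation()] with attribute `report`: a list with
#'   `n_detected`, `n_dropped`, `tail_breath` (index of the final,
#'   end-of-record breath, or NA).
#' @export
#' @examples
#' synth <- clean_breath_signal(synthetic_spec(f1_bpm = 12, fs = 100,
#'                                             noise_level = 0), 5)
#' ann <- detect_breaths(synth$clean)
#' ann
detect_breaths <- function(signal, config = detection_config()) {
  validate_signal(signal)
  insp <- detect_inspiratory_onsets(signal, config)
  if (length(insp) < 2L) {
    ann <- breath_annotation(integer(0), integer(0), signal$fs)
    attr(ann, "report") <- list(n_detected = 0L, n_dropped = 0L,
                                tail_breath = NA_integer_)
    return(ann)
  }
  expo <- detect_expiratory_onsets(signal, insp, config)
  ok <- !is.na(expo) & expo > insp
  ann <- breath_annotation(insp[ok], expo[ok], signal$fs,
                           n_samples = length(signal$values))
  attr(ann, "report") <- list(
    n_detected = sum(ok),
    n_dropped = sum(!ok),
    tail_breath = if (ok[length(ok)]) sum(ok) else NA_integer_
  )
  ann
}
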