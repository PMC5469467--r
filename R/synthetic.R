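#' Specification of the synthetic flow-signal model
#'
#' Collects every parameter of the gated-sinusoid flow model and its
#' disturbances. The clean signal is
#' \deqn{X(t) = Y(t) A_1 \sin(2\pi f_1 t / f_s + \phi) +
#'       A_2 \cos(2\pi f_1 t / f_s + \phi)}
#' with `t` in samples and `Y` a square wave (duty cycle 50% by default)
#' equal to 1 during inspiration, gating the large sine half-wave on top of a
#' small cosine; each gate opening produces a slope discontinuity (the
#' inspiratory-onset kink). Disturbances follow
#' \deqn{X_{noisy}(t) = [X(t) + \xi_n][1 + A_m \sin(2\pi f_m t / f_s + \phi)]
#'       + \xi_{trend}}
#' where `xi_n` is white Gaussian noise with SD `noise_level * sqrt(A1)`,
#' the sine factor is a slow amplitude modulation, and `xi_trend` is a
#' fractional-Gaussian-noise baseline trend (SD 0.1, Hurst 0.9) sampled once
#' per breath and linearly interpolated, emulating breath-by-breath baseline
#' wander (see the methods vignette for the reasoning behind both noise
#' conventions and the `noise_sd_mode` / `trend_per` alternatives).
#'
#' @param f1_bpm Breathing frequency in breaths/min (converted to Hz
#'   internally, `f1 = f1_bpm / 60`).
#' @param fs Sampling frequency in Hz; must exceed `2 * f1`.
#' @param A1 Amplitude of the gated sine carrier (L/s), default 0.25.
#' @param A2 Amplitude of the cosine carrier (L/s), default 0.1.
#' @param phi Initial phase in radians, in `[0, 2*pi)`. Default 0 (an
#'   inspiratory onset at the first sample).
#' @param noise_level White-noise level as a fraction (0.02 = 2%).
#' @param Am Amplitude-modulation depth, default 0.5.
#' @param fm Amplitude-modulation frequency in Hz, default 0.005.
#' @param trend_sd Baseline-trend standard deviation, default 0.1.
#' @param hurst Hurst exponent of the trend in (0, 1), default 0.9.
#' @param duty_cycle Inspiratory fraction of the breath period, default 0.5.
#' @param noise_sd_mode `"constant"` (default): white-noise SD equals
#'   `noise_level * sqrt(A1)`; `"instantaneous"`: per-sample SD
#'   `noise_level * sqrt(|X(t)|)`.
#' @param trend_per `"breath"` (default): one FGN value per breath, linearly
#'   interpolated; `"sample"`: FGN at full sample resolution.
#' @param seed Optional integer seed for all randomness in the generator.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(f1_bpm = 15, fs = 250, A1 = 0.25, A2 = 0.1,
                           phi = 0, noise_level = 0.02, Am = 0.5, fm = 0.005,
                           trend_sd = 0.1, hurst = 0.9, duty_cycle = 0.5,
                           noise_sd_mode = c("constant", "instantaneous"),
                           trend_per = c("breath", "sample"), seed = NULL) {
  noise_sd_mode <- match.arg(noise_sd_mode)
  trend_per <- match.arg(trend_per)
  f1 <- f1_bpm / 60
  if (!(hurst > 0 && hurst < 1)) {
    stop("config error: `hurst` must be in (0, 1)", call. = FALSE)
  }
  if (duty_cycle < 0 || duty_cycle > 1) {
    stop("config error: `duty_cycle` must be in [0, 1]", call. = FALSE)
  }
  if (fs <= 2 * f1) {
    stop("aliasing error: `fs` must exceed twice the breathing frequency",
         call. = FALSE)
  }
  if (noise_level < 0) {
    stop("config error: `noise_level` must be >= 0", call. = FALSE)
  }
  structure(
    list(f1_bpm = f1_bpm, f1 = f1, fs = fs, A1 = A1, A2 = A2, phi = phi,
         noise_level = noise_level, Am = Am, fm = fm, trend_sd = trend_sd,
         hurst = hurst, duty_cycle = duty_cycle,
         noise_sd_mode = noise_sd_mode, trend_per = trend_per, seed = seed),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_spec> %g bpm @ %g Hz  A1=%g A2=%g phi=%.3f\n",
           "  noise=%g%% (%s)  Am=%g fm=%g Hz  trend sd=%g H=%g (%s)\n"),
    x$f1_bpm, x$fs, x$A1, x$A2, x$phi,
    100 * x$noise_level, x$noise_sd_mode, x$Am, x$fm, x$trend_sd, x$hurst,
    x$trend_per
  ))
  invisible(x)
}

#' Noise-free gated-sinusoid breath signal with ground truth
#'
#' Evaluates the clean model (see [synthetic_spec()]) over `n_breaths` full
#' breath periods. Truth inspiratory onsets sit at the square wave's 0 -> 1
#' transitions (where the gated sine switches on and the slope jumps); truth
#' expiratory onsets are located on the clean signal by the same
#' drift-corrected volume-maximum rule the detector uses, because the kink is
#' the only structural landmark the model defines for inspiration while
#' expiration is defined functionally.
#'
#' @param spec A [synthetic_spec()].
#' @param n_breaths Number of breaths (>= 1).
#' @return An object of class `synthetic_signal`: list with `clean`,
#'   `reference` and `noisy` [sampled_signal()]s (all equal here), `truth`
#'   (a [breath_annotation()]) and `spec`. `reference` is the
#'   amplitude-modulated noise-free signal once [add_disturbances()] has run.
#' @export
#' @examples
#' s <- clean_breath_signal(synthetic_spec(f1_bpm = 10, fs = 100), n_breaths = 3)
#' s$truth
clean_breath_signal <- function(spec, n_breaths) {
  if (n_breaths < 1) stop("config error: `n_breaths` must be >= 1", call. = FALSE)
  period <- spec$fs / spec$f1 # samples per breath
  n <- round(n_breaths * period)
  t <- 0:(n - 1L)
  x <- model_flow(t, spec)
  insp <- gate_transitions(t, spec)
  if (length(insp) != n_breaths) {
    # guard against boundary rounding: keep the first n_breaths onsets
    insp <- insp[seq_len(min(n_breaths, length(insp)))]
  }
  clean <- sampled_signal(x, spec$fs, kind = "flow")
  truth <- truth_annotation(clean, insp)
  structure(
    list(clean = clean, reference = clean, noisy = clean, truth = truth,
         spec = spec),
    class = "synthetic_signal"
  )
}

# clean flow: gated sine + cosine (t in samples)
model_flow <- function(t, spec) {
  theta <- 2 * pi * spec$f1 * t / spec$fs + spec$phi
  gate <- square_gate(t, spec)
  gate * spec$A1 * sin(theta) + spec$A2 * cos(theta)
}

# phase fraction in [0, 1): computed directly from t / period (plus the
# phase offset) so that integer-period boundaries are exact in floating
# point; going through sin(theta) would jitter boundary samples by 1.
phase_frac <- function(t, spec) {
  period <- spec$fs / spec$f1
  (t / period + spec$phi / (2 * pi)) %% 1
}

# square wave: 1 during inspiration, i.e. phase fraction in [0, duty);
# the boundary sample itself (sin = 0, rising) belongs to inspiration
square_gate <- function(t, spec) {
  as.numeric(phase_frac(t, spec) < spec$duty_cycle)
}

# 0-based indices of the square wave's 0 -> 1 transitions; a t = 0 start
# exactly at a period boundary counts as an onset.
gate_transitions <- function(t, spec) {
  gate <- square_gate(t, spec)
  trans <- which(diff(gate) == 1) # 0-based index of the first gate==1 sample
  if (gate[1L] == 1 && phase_frac(t[1L], spec) == 0) trans <- c(0L, trans)
  as.integer(trans)
}

# Build the truth annotation: expiratory onsets by the drift-corrected
# volume-maximum rule applied to `ref_signal` between adjacent onsets
# (to end of record for the last breath).
truth_annotation <- function(ref_signal, insp) {
  n <- length(ref_signal$values)
  ends <- c(insp[-1L], n - 1L)
  expo <- integer(length(insp))
  for (k in seq_along(insp)) {
    expo[k] <- volume_peak_index(ref_signal, insp[k], ends[k])
  }
  breath_annotation(insp, expo, ref_signal$fs, n_samples = n)
}

#' Add noise, amplitude modulation and baseline trend to a clean signal
#'
#' Applies the disturbance model: white noise added to the clean signal, the
#' sum multiplied by the slow amplitude modulation, and the
#' fractional-Gaussian-noise baseline trend added last (so the trend acts as
#' a baseline drift rather than being modulated). The amplitude-modulated
#' noise-free signal is stored as `reference` and truth expiratory onsets are
#' recomputed on it; truth inspiratory onsets are unchanged (modulation does
#' not move the kink).
#'
#' @param synth A `synthetic_signal` from [clean_breath_signal()].
#' @param spec Optional [synthetic_spec()] overriding `synth$spec`.
#' @return The `synthetic_signal` with `noisy`, `reference` and `truth`
#'   updated.
#' @export
add_disturbances <- function(synth, spec = NULL) {
  if (is.null(spec)) spec <- synth$spec
  if (!is.null(spec$seed)) {
    return(with_local_seed(spec$seed, add_disturbances_impl(synth, spec)))
  }
  add_disturbances_impl(synth, spec)
}

add_disturbances_impl <- function(synth, spec) {
  x <- synth$clean$values
  n <- length(x)
  t <- 0:(n - 1L)
  modulation <- 1 + spec$Am * sin(2 * pi * spec$fm * t / spec$fs + spec$phi)

  if (spec$noise_level > 0) {
    sd_n <- if (spec$noise_sd_mode == "constant") {
      spec$noise_level * sqrt(spec$A1)
    } else {
      spec$noise_level * sqrt(abs(x))
    }
    noise <- stats::rnorm(n, sd = sd_n)
  } else {
    noise <- 0
  }

  trend <- synth_trend(spec, n, synth$truth$insp_onset_idx)
  noisy <- (x + noise) * modulation + trend
  reference <- sampled_signal(x * modulation, spec$fs, kind = "flow")

  synth$noisy <- sampled_signal(noisy, spec$fs, kind = "flow")
  synth$reference <- reference
  synth$truth <- truth_annotation(reference, synth$truth$insp_onset_idx)
  synth$spec <- spec
  synth
}

# FGN baseline trend: one knot per breath (at the true inspiratory onsets,
# plus the record ends), linearly interpolated to sample resolution; or, for
# trend_per = "sample", FGN at full resolution.
synth_trend <- function(spec, n, insp_onsets) {
  if (spec$trend_sd <= 0) return(rep(0, n))
  if (spec$trend_per == "sample") {
    return(fractional_gaussian_noise(n, spec$hurst, spec$trend_sd))
  }
  knots_t <- insp_onsets
  if (length(knots_t) == 0L || knots_t[1L] > 0L) knots_t <- c(0L, knots_t)
  if (knots_t[length(knots_t)] < n - 1L) knots_t <- c(knots_t, n - 1L)
  if (length(knots_t) < 2L) knots_t <- c(0L, n - 1L)
  vals <- fractional_gaussian_noise(length(knots_t), spec$hurst, spec$trend_sd)
  stats::approx(knots_t, vals, xout = 0:(n - 1L), rule = 2)$y
}

#' @export
print.synthetic_signal <- function(x, ...) {
  cat(sprintf("<synthetic_signal> %d breaths  n=%d samples  fs=%g Hz\n",
              length(x$truth$insp_onset_idx), length(x$clean$values),
              x$clean$fs))
  invisible(x)
}

#' Amplitude-modulated noise-free reference signal
#'
#' The reference channel against which detector output is scored: the clean
#' gated sinusoid times the amplitude modulation, with no white noise and no
#' baseline trend. True respiratory parameters are computed from this signal.
#'
#' @param synth A `synthetic_signal`.
#' @return A [sampled_signal()].
#' @export
reference_signal <- function(synth) synth$reference

#' Generate the 1000-breath validation dataset
#'
#' Concatenates ten constant-frequency segments, one per breathing frequency
#' from 8 to 17 breaths/min, each containing `n_breaths_per_segment` breaths
#' (100 by default, 1000 breaths total). Every segment starts at carrier
#' phase 0 and spans an integer number of breath periods, so the clean signal
#' is continuous across segment boundaries and each boundary is itself a true
#' inspiratory onset. The disturbances are applied once to the whole
#' concatenated record — one white-noise stream, one amplitude-modulation
#' sinusoid on the global time base, and one per-breath FGN trend with knots
#' at the 1000 true onsets — so no artificial discontinuities are introduced
#' at segment boundaries.
#'
#' @param fs Sampling frequency in Hz (the study grid uses 50, 100, 250, 500,
#'   1000; any value above twice the fastest breathing frequency works).
#' @param noise_level White-noise fraction (0.02 = 2%).
#' @param seed Integer seed making the dataset reproducible.
#' @param n_breaths_per_segment Breaths per frequency segment (default 100).
#' @param f1_grid_bpm Breathing frequencies in breaths/min (default 8:17).
#' @param ... Further arguments passed to [synthetic_spec()] (e.g. `Am`,
#'   `trend_sd`, `hurst`).
#' @return A `synthetic_signal` covering the whole concatenated record.
#' @export
#' @examples
#' ds <- generate_validation_dataset(fs = 50, noise_level = 0, seed = 1,
#'                                   n_breaths_per_segment = 2)
#' length(ds$truth$insp_onset_idx) # 20
generate_validation_dataset <- function(fs, noise_level, seed = NULL,
                                        n_breaths_per_segment = 100,
                                        f1_grid_bpm = 8:17, ...) {
  run <- function() {
    clean <- list()
    insp <- integer(0)
    offset <- 0L
    for (bpm in f1_grid_bpm) {
      spec <- synthetic_spec(f1_bpm = bpm, fs = fs, noise_level = noise_level,
                             phi = 0, seed = NULL, ...)
      period <- fs / spec$f1
      n_seg <- round(n_breaths_per_segment * period)
      t <- 0:(n_seg - 1L)
      clean[[length(clean) + 1L]] <- model_flow(t, spec)
      insp <- c(insp, gate_transitions(t, spec)[
        seq_len(n_breaths_per_segment)] + offset)
      offset <- offset + n_seg
    }
    spec_global <- synthetic_spec(f1_bpm = f1_grid_bpm[1L], fs = fs,
                                  noise_level = noise_level, phi = 0,
                                  seed = NULL, ...)
    clean_sig <- sampled_signal(unlist(clean), fs, kind = "flow")
    synth <- structure(
      list(clean = clean_sig, reference = clean_sig, noisy = clean_sig,
           truth = breath_annotation(insp, insp + 1L, fs),
           spec = spec_global),
      class = "synthetic_signal"
    )
    add_disturbances_impl(synth, spec_global)
  }
  if (!is.null(seed)) with_local_seed(seed, run()) else run()
}
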