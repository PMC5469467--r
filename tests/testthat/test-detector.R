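test_that("find_extrema locates sine peaks at their analytic positions", {
  fs <- 250
  t <- (0:(60 * fs - 1)) / fs
  sig <- sampled_signal(sin(2 * pi * 0.2 * t), fs)
  ext <- find_extrema(sig)
  # peaks at t = 1.25 + 5k: 12 peaks in 60 s
  expect_length(ext$peaks, 12)
  expect_true(all(abs(ext$peaks - (1.25 + 5 * (0:11)) * fs) <= 2))
  # valleys interleave
  expect_length(ext$valleys, 12)
  expect_true(all(ext$valleys > head(ext$peaks, 12) - 5 * fs))
  both <- sort(c(ext$peaks, ext$valleys))
  types <- ifelse(both %in% ext$peaks, 1, -1)
  expect_true(all(diff(types) != 0)) # strict alternation
})

test_that("peak separation keeps the taller of two close maxima", {
  fs <- 100
  t <- (0:999) / fs
  # two bumps 0.5 s apart, the second one taller
  x <- exp(-((t - 4.0) / 0.1)^2) + 1.5 * exp(-((t - 4.5) / 0.1)^2)
  ext <- find_extrema(sampled_signal(x, fs),
                      detection_config(cutoff_hz = 10, min_breath_s = 1))
  near <- ext$peaks[ext$peaks > 3.5 * fs & ext$peaks < 5 * fs]
  expect_length(near, 1)
  expect_lt(abs(near - 4.5 * fs), 10)
})

test_that("flat or empty-structure signals yield no extrema, no breaths", {
  flat <- sampled_signal(rep(1, 1000), fs = 100)
  ext <- find_extrema(flat)
  expect_length(ext$peaks, 0)
  ann <- detect_breaths(flat)
  expect_length(ann, 0)
  expect_equal(attr(ann, "report")$n_detected, 0)
})

test_that("onset segments bracket the square-wave transition (flow mode)", {
  s <- clean_case(bpm = 12, fs = 250, n_breaths = 5)
  ext <- find_extrema(s$clean)
  segs <- extract_onset_segments(s$clean, ext$peaks, ext$valleys)
  expect_equal(segs$n_skipped, 0)
  period <- 1250
  transitions <- period * (1:4)
  for (k in seq_along(segs$segments)) {
    seg <- segs$segments[[k]]
    expect_lt(seg[1], transitions[k])
    expect_gt(seg[2], transitions[k])
  }
  # truncated record: final unpaired valley produces no segment
  expect_lte(length(segs$segments), length(ext$valleys))
})

test_that("pepi-mode segments mirror flow-mode segments on the negated model", {
  s <- clean_case(bpm = 12, fs = 250, n_breaths = 5)
  neg <- sampled_signal(-s$clean$values, 250, kind = "pressure")
  ext_f <- find_extrema(s$clean)
  ext_p <- find_extrema(neg)
  expect_equal(ext_p$peaks, ext_f$valleys)
  expect_equal(ext_p$valleys, ext_f$peaks)
  segs_f <- extract_onset_segments(s$clean, ext_f$peaks, ext_f$valleys,
                                   detection_config(signal_kind = "flow"))
  segs_p <- extract_onset_segments(neg, ext_p$peaks, ext_p$valleys,
                                   detection_config(signal_kind = "pepi"))
  expect_equal(segs_p$segments, segs_f$segments)
})

test_that("locate_inflection agrees with the finite-difference oracle on
           clean rising limbs", {
  for (fs in c(100, 250, 500)) {
    s <- clean_case(bpm = 12, fs = fs, n_breaths = 4)
    ext <- find_extrema(s$clean)
    segs <- extract_onset_segments(s$clean, ext$peaks, ext$valleys)$segments
    for (seg in segs) {
      spl <- locate_inflection(s$clean, seg)
      fd <- fd_inflection_argmax(s$clean$values, seg)
      expect_lte(abs(spl - fd), 2)
      # and the FD oracle itself sits at the square-wave transition
      period <- fs * 60 / 12
      expect_lte(min(abs(fd - period * (1:4))), 1)
    }
  }
})

test_that("locate_inflection handles degenerate and tiny segments", {
  const <- sampled_signal(rep(2, 100), fs = 50)
  expect_true(is.na(locate_inflection(const, c(10L, 60L))))
  expect_error(smoothing_spline(rep(1, 3), 1, 0.95), ">= 4")
})

test_that("detected inspiratory onsets are strictly increasing and spaced", {
  s <- clean_case(bpm = 15, fs = 125, n_breaths = 8)
  on <- detect_inspiratory_onsets(s$clean)
  expect_true(all(diff(on) > 0))
  expect_true(all(diff(on) >= 1 * 125))
})

test_that("detection is shift-equivariant", {
  s <- clean_case(bpm = 12, fs = 100, n_breaths = 5)
  base <- detect_inspiratory_onsets(s$clean)
  k <- 137L
  shifted <- sampled_signal(c(rep(s$clean$values[1], k), s$clean$values), 100)
  expect_equal(detect_inspiratory_onsets(shifted), base + k)
})

test_that("detection is amplitude-scale invariant on the clean model", {
  s <- clean_case(bpm = 10, fs = 125, n_breaths = 5)
  base <- detect_inspiratory_onsets(s$clean)
  doubled <- sampled_signal(2 * s$clean$values, 125)
  expect_equal(detect_inspiratory_onsets(doubled), base)
})

test_that("flow-mode expiratory onsets match the brute-force volume oracle", {
  s <- clean_case(bpm = 10, fs = 125, n_breaths = 5)
  insp <- s$truth$insp_onset_idx
  expo <- detect_expiratory_onsets(s$clean, insp)
  n <- length(s$clean$values)
  ends <- c(insp[-1], n - 1)
  oracle <- mapply(function(a, b) {
    brute_volume_argmax(s$clean$values, 125, a, b)
  }, insp, ends)
  expect_equal(expo, as.integer(oracle))
  # each expiratory onset strictly inside its breath
  expect_true(all(expo > insp & expo <= ends))
})

test_that("rectangular flow: expiratory onset exactly at the sign flip", {
  fs <- 250
  x <- rep(c(rep(0.5, 2 * fs), rep(-0.5, 2 * fs)), 3)
  sig <- sampled_signal(x, fs)
  insp <- as.integer(4 * fs * (0:2))
  expo <- detect_expiratory_onsets(sig, insp)
  # at the sign flip, up to the half-sample trapezoid tie broken earliest
  expect_true(all(abs(expo[1:2] - (insp[1:2] + 2L * fs)) <= 1))
})

test_that("pepi-mode expiratory onset: horizontal-line case and nadir rule", {
  fs <- 100
  # V-shaped breaths with equal endpoint values -> line is horizontal;
  # crossing where the waveform returns to the endpoint level
  one <- c(seq(0, -1, length.out = 50), seq(-1, 0, length.out = 50),
           rep(0, 100))
  x <- c(rep(one, 3), 0)
  sig <- sampled_signal(x, fs, kind = "pressure")
  insp <- as.integer(200 * (0:2))
  expo <- detect_expiratory_onsets(sig, insp,
                                   detection_config(signal_kind = "pepi"))
  # nadir at +49; first return to the endpoint level (0) at +99
  expect_equal(expo[1:2], insp[1:2] + 99L)
  # tail breath uses the mean slope of prior lines (horizontal here)
  expect_equal(expo[3], insp[3] + 99L)
})

test_that("detect_breaths drops unresolved breaths and reports counts", {
  s <- clean_case(bpm = 12, fs = 125, n_breaths = 10)
  ann <- detect_breaths(s$clean)
  rep <- attr(ann, "report")
  expect_gte(rep$n_detected, 8)
  expect_true(all(ann$insp_onset_idx < ann$exp_onset_idx))
  # annotation invariants hold
  expect_s3_class(validate_signal(s$clean), "sampled_signal")
  expect_true(all(diff(ann$insp_onset_idx) > 0))
})

test_that("baseline drift immunity: pure smooth trend barely moves onsets", {
  s <- clean_case(bpm = 12, fs = 250, n_breaths = 6)
  base <- detect_inspiratory_onsets(s$clean)
  spec <- synthetic_spec(f1_bpm = 12, fs = 250, noise_level = 0, Am = 0,
                         trend_sd = 0.1, hurst = 0.9, seed = 17)
  drifted <- add_disturbances(clean_breath_signal(spec, 6))
  on <- detect_inspiratory_onsets(drifted$noisy)
  expect_equal(length(on), length(base))
  expect_true(all(abs(on - base) <= 2))
})
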