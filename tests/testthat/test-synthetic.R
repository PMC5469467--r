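test_that("clean model evaluates the gated-sinusoid closed form", {
  spec <- synthetic_spec(f1_bpm = 12, fs = 250, noise_level = 0, phi = 0)
  s <- clean_breath_signal(spec, 3)
  x <- s$clean$values
  period <- 250 * 60 / 12 # 1250 samples
  theta <- 2 * pi * (0:(length(x) - 1)) / period
  gate <- ifelse(theta %% (2 * pi) < pi, 1, 0)
  expect_equal(x, gate * 0.25 * sin(theta) + 0.1 * cos(theta),
               tolerance = 1e-12)
  # continuity with value A2 at the gate opening; slope jumps by ~A1*w
  k <- period # first 0 -> 1 transition after t = 0
  expect_equal(x[k + 1], 0.1, tolerance = 1e-6)
  slope_before <- x[k + 1] - x[k]
  slope_after <- x[k + 2] - x[k + 1]
  expect_gt(slope_after - slope_before, 0.8 * 0.25 * 2 * pi / period)
  # bounded by |A1| + |A2|
  expect_lte(max(abs(x)), 0.25 + 0.1 + 1e-12)
})

test_that("duty cycle 50%: inspiration occupies exactly half of each period", {
  spec <- synthetic_spec(f1_bpm = 10, fs = 100, noise_level = 0)
  s <- clean_breath_signal(spec, 5)
  period <- 100 * 60 / 10
  theta <- 2 * pi * (0:(length(s$clean$values) - 1)) / period
  gate <- as.numeric(sin(theta) >= 0)
  expect_equal(mean(gate), 0.5, tolerance = 1e-3)
  # truth onsets exactly one period apart (integer-period case)
  expect_equal(diff(s$truth$insp_onset_idx), rep(period, 4))
})

test_that("truth breath count equals the requested count", {
  for (bpm in c(8, 13, 17)) {
    s <- clean_case(bpm = bpm, fs = 125, n_breaths = 7)
    expect_length(s$truth$insp_onset_idx, 7)
  }
  expect_error(clean_breath_signal(synthetic_spec(), 0), "n_breaths")
})

test_that("A1 = 0 degenerates to a pure cosine without kinks", {
  s <- clean_case(bpm = 10, fs = 100, n_breaths = 4, A1 = 0)
  theta <- 2 * pi * (0:(length(s$clean$values) - 1)) / (100 * 60 / 10)
  expect_equal(s$clean$values, 0.1 * cos(theta), tolerance = 1e-12)
  expect_length(s$truth$insp_onset_idx, 4)
})

test_that("disturbance identity: no noise, no modulation, no trend", {
  s <- clean_case(bpm = 12, fs = 100, n_breaths = 4,
                  Am = 0, trend_sd = 0)
  out <- add_disturbances(s)
  expect_identical(out$noisy$values, out$clean$values)
  expect_identical(out$reference$values, out$clean$values)
})

test_that("amplitude modulation multiplies the clean signal as specified", {
  spec <- synthetic_spec(f1_bpm = 12, fs = 100, noise_level = 0,
                         Am = 0.5, fm = 0.05, trend_sd = 0, seed = 1)
  s <- add_disturbances(clean_breath_signal(spec, 10))
  n <- length(s$clean$values)
  modulation <- 1 + 0.5 * sin(2 * pi * 0.05 * (0:(n - 1)) / 100)
  expect_equal(s$noisy$values, s$clean$values * modulation, tolerance = 1e-12)
  expect_true(all(modulation >= 0.5 & modulation <= 1.5))
  # truth inspiratory onsets unchanged by modulation
  expect_identical(s$truth$insp_onset_idx,
                   clean_breath_signal(spec, 10)$truth$insp_onset_idx)
})

test_that("white-noise SD follows the noise level times sqrt(A1)", {
  spec <- synthetic_spec(f1_bpm = 12, fs = 250, noise_level = 0.02,
                         Am = 0, trend_sd = 0, seed = 8)
  s <- add_disturbances(clean_breath_signal(spec, 40))
  resid <- s$noisy$values - s$clean$values
  expect_equal(sd(resid), 0.02 * sqrt(0.25), tolerance = 0.05)
})

test_that("trend component reconstructs from the same seed", {
  spec <- synthetic_spec(f1_bpm = 12, fs = 100, noise_level = 0,
                         Am = 0, trend_sd = 0.1, hurst = 0.9, seed = 21)
  s <- add_disturbances(clean_breath_signal(spec, 20))
  trend <- s$noisy$values - s$clean$values
  # per-breath knots, linear in between: second differences vanish away
  # from knots
  d2 <- diff(diff(trend))
  expect_lt(median(abs(d2)), 1e-10)
  # marginal scale of the trend is the FGN sd
  expect_equal(sd(trend), 0.1, tolerance = 0.6)
  # same seed, same trend
  s2 <- add_disturbances(clean_breath_signal(spec, 20))
  expect_identical(s2$noisy$values, s$noisy$values)
})

test_that("validation dataset has the stated structure", {
  ds <- generate_validation_dataset(fs = 50, noise_level = 0.02, seed = 4,
                                    n_breaths_per_segment = 3)
  expect_length(ds$truth$insp_onset_idx, 30)
  # segment duration: n * 60 / bpm seconds each
  expected_n <- sum(round(3 * 50 * 60 / (8:17)))
  expect_length(ds$noisy$values, expected_n)
  # reproducible
  ds2 <- generate_validation_dataset(fs = 50, noise_level = 0.02, seed = 4,
                                     n_breaths_per_segment = 3)
  expect_identical(ds$noisy$values, ds2$noisy$values)
  expect_identical(ds$truth$insp_onset_idx, ds2$truth$insp_onset_idx)
  # different seed differs
  ds3 <- generate_validation_dataset(fs = 50, noise_level = 0.02, seed = 5,
                                     n_breaths_per_segment = 3)
  expect_false(identical(ds$noisy$values, ds3$noisy$values))
})

test_that("truth onset spacing within a segment is exactly fs * 60 / bpm", {
  ds <- generate_validation_dataset(fs = 120, noise_level = 0, seed = 1,
                                    n_breaths_per_segment = 4,
                                    f1_grid_bpm = c(8, 10, 12))
  gaps <- diff(ds$truth$insp_onset_idx)
  # within segments (3 gaps each of the first two segments are clean checks)
  expect_equal(gaps[1:3], rep(120 * 60 / 8, 3))
  expect_equal(gaps[5:7], rep(120 * 60 / 10, 3))
  expect_equal(gaps[9:11], rep(120 * 60 / 12, 3))
})

test_that("aliasing and parameter guards fire", {
  expect_error(synthetic_spec(f1_bpm = 60, fs = 1.5), "aliasing")
  expect_error(synthetic_spec(hurst = 1.2), "hurst")
  expect_error(synthetic_spec(noise_level = -0.1), "noise_level")
  expect_error(synthetic_spec(duty_cycle = 1.4), "duty_cycle")
})
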