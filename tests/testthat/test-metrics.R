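test_that("rectangular breath yields textbook parameter values", {
  fs <- 250
  x <- c(rep(0.5, 2 * fs), rep(-0.5, 2 * fs), rep(0.5, 2 * fs),
         rep(-0.5, 2 * fs), 0.5)
  fl <- sampled_signal(x, fs)
  ann <- breath_annotation(c(0L, 4L * fs), c(2L * fs, 6L * fs), fs)
  p <- compute_params(fl, ann)
  expect_equal(p$Ti[1], 2)
  expect_equal(p$Te[1], 2)
  expect_equal(p$Ttot[1], 4)
  expect_equal(p$PIF[1], 0.5)
  # Vt/Vi exact up to the half-sample trapezoid edge of the step waveform
  expect_equal(p$Vt[1], 1.0, tolerance = 0.005)
  expect_equal(p$Vi[1], 15.0, tolerance = 0.005)
  # Vt = PIF * Ti for rectangular flow
  expect_equal(p$Vt[1], p$PIF[1] * p$Ti[1], tolerance = 0.005)
  # last breath: Te/Ttot/Vi undefined, flagged as tail
  expect_true(is.na(p$Te[2]) && is.na(p$Ttot[2]) && is.na(p$Vi[2]))
  expect_true(p$tail[2])
  # Ttot = Ti + Te to machine precision where defined
  expect_identical(p$Ttot[1], p$Ti[1] + p$Te[1])
})

test_that("zero-flow breath gives zero PIF, Vt, Vi", {
  fs <- 100
  fl <- sampled_signal(numeric(1000), fs)
  ann <- breath_annotation(c(0L, 500L), c(250L, 750L), fs)
  p <- compute_params(fl, ann)
  expect_equal(p$PIF[1], 0)
  expect_equal(p$Vt[1], 0)
  expect_equal(p$Vi[1], 0)
})

test_that("clean model parameters match a closed-form/brute-force oracle", {
  fs <- 250; bpm <- 10
  s <- clean_case(bpm = bpm, fs = fs, n_breaths = 5)
  p <- compute_params(s$clean, s$truth)
  period_s <- 60 / bpm
  # truth expiratory onset = brute-force argmax of corrected volume
  a <- s$truth$insp_onset_idx[1]; b <- s$truth$insp_onset_idx[2]
  exp_oracle <- brute_volume_argmax(s$clean$values, fs, a, b)
  expect_equal(s$truth$exp_onset_idx[1], as.integer(exp_oracle))
  expect_equal(p$Ti[1], (exp_oracle - a) / fs)
  expect_equal(p$Ttot[1], period_s, tolerance = 1e-6)
  # PIF: max of (flow - per-breath mean flow); closed form for the model
  flow_fun <- function(th) ifelse(sin(th) >= 0, 0.25 * sin(th), 0) +
    0.1 * cos(th)
  mean_flow <- riemann_integral(function(u) flow_fun(2 * pi * u / period_s),
                                period_s) / period_s
  pif_closed <- sqrt(0.25^2 + 0.1^2) - mean_flow
  expect_equal(p$PIF[1], pif_closed, tolerance = 1e-3)
})

test_that("Vi is invariant to sampling frequency", {
  p_lo <- compute_params(clean_case(bpm = 12, fs = 250)$clean,
                         clean_case(bpm = 12, fs = 250)$truth)
  p_hi <- compute_params(clean_case(bpm = 12, fs = 1000)$clean,
                         clean_case(bpm = 12, fs = 1000)$truth)
  expect_equal(p_lo$Vi[1:4], p_hi$Vi[1:4], tolerance = 1e-3)
})

test_that("total breath time never exceeds the record duration", {
  s <- clean_case(bpm = 15, fs = 125, n_breaths = 8)
  p <- compute_params(s$clean, s$truth)
  expect_lte(sum(p$Ttot, na.rm = TRUE), length(s$clean$values) / 125)
})

test_that("nadir pressure is taken over inspiration", {
  fs <- 100
  pepi_vals <- rep(0, 1000)
  pepi_vals[101:200] <- -seq(1, 5, length.out = 100) # dip inside insp 1
  pepi_vals[451:500] <- -10                          # deeper dip in exp 1
  fl <- sampled_signal(rep(c(0.5, -0.5), each = 5, times = 100), fs)
  pepi <- sampled_signal(pepi_vals, fs, kind = "pressure")
  ann <- breath_annotation(c(0L, 600L), c(300L, 900L), fs)
  p <- compute_params(fl, ann, pepi = pepi)
  expect_equal(p$nadir_pepi[1], -5)
  p_breath <- compute_params(fl, ann, pepi = pepi, nadir_over = "breath")
  expect_equal(p_breath$nadir_pepi[1], -10)
})

test_that("inverted transducers are handled by sign flip", {
  fs <- 100
  x <- c(rep(-0.5, 200), rep(0.5, 200), rep(-0.5, 200), 0)
  fl <- sampled_signal(x, fs)
  ann <- breath_annotation(c(0L, 400L), c(200L, 600L), fs)
  p <- compute_params(fl, ann, invert_flow = TRUE)
  expect_equal(p$PIF[1], 0.5)
  expect_equal(p$Vt[1], 1.0, tolerance = 0.01)
})

test_that("summaries use the sample SD and report n", {
  fs <- 100
  fl <- sampled_signal(rep(0.5, 1500), fs)
  ann <- breath_annotation(c(0L, 200L, 600L), c(100L, 400L, 1000L), fs)
  p <- compute_params(fl, ann)
  sm <- summarize_params(p)
  ti <- sm[sm$parameter == "Ti", ]
  expect_equal(ti$mean, mean(c(1, 2, 4)))
  expect_equal(ti$sd, sd(c(1, 2, 4)))
  expect_equal(ti$n, 3)
  # Ti = {2, 4} style two-breath check: mean 3, sd sqrt(2)
  two <- summarize_params(p[2:3, ])
  expect_equal(two[two$parameter == "Ti", ]$mean, 3)
  expect_equal(two[two$parameter == "Ti", ]$sd, sqrt(2))
  # single breath: SD 0
  one <- summarize_params(p[1, ])
  expect_equal(one[one$parameter == "Ti", ]$sd, 0)
  # empty input: empty summary
  expect_equal(nrow(summarize_params(p[0, ])), 0)
})

test_that("consistency errors are raised for mismatched inputs", {
  fl <- sampled_signal(rep(0.5, 100), 100)
  ann <- breath_annotation(0L, 50L, fs = 250)
  expect_error(compute_params(fl, ann), "sampling rates")
  ann2 <- breath_annotation(0L, 99L, fs = 100)
  pepi_short <- sampled_signal(rep(0, 50), 100, kind = "pressure")
  expect_error(compute_params(fl, ann2, pepi = pepi_short), "match")
})
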