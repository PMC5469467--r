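#' Match detected breaths to reference breaths
#'
#' Greedy nearest-neighbor matching on inspiratory onset times: candidate
#' (detected, reference) pairs within `tolerance_s` are accepted in order of
#' increasing absolute time difference, each onset used at most once.
#' Reference onsets left unmatched are missed breaths; unmatched detections
#' are counted as false positives. Expiratory onsets are compared within the
#' matched pairs.
#'
#' @param detected,reference [breath_annotation()]s on the same sampling
#'   frequency.
#' @param tolerance_s Matching tolerance in seconds (default 0.5, half the
#'   minimum breath duration).
#' @return A list of class `onset_match`: `pairs` (data.frame with 1-based
#'   breath indices `det`, `ref` and onset errors in seconds
#'   `insp_error_s`, `exp_error_s` = detected - reference),
#'   `missed_ref` / `false_pos_det` (1-based indices), `n_reference`,
#'   `n_matched`, `missed_pct`.
#' @export
match_onsets <- function(detected, reference, tolerance_s = 0.5) {
  if (!isTRUE(all.equal(detected$fs, reference$fs))) {
    stop("consistency error: annotations have different sampling rates",
         call. = FALSE)
  }
  fs <- reference$fs
  dt <- detected$insp_onset_idx / fs
  rt <- reference$insp_onset_idx / fs
  nd <- length(dt); nr <- length(rt)
  pairs <- data.frame(det = integer(0), ref = integer(0),
                      insp_error_s = numeric(0), exp_error_s = numeric(0))
  if (nd > 0L && nr > 0L) {
    # candidate pairs: for each reference onset, its sorted-order neighbors
    pos <- findInterval(rt, dt)
    cand <- rbind(
      data.frame(det = pmax(pos, 1L), ref = seq_len(nr)),
      data.frame(det = pmin(pos + 1L, nd), ref = seq_len(nr))
    )
    cand <- unique(cand[cand$det >= 1L & cand$det <= nd, ])
    cand$diff <- abs(dt[cand$det] - rt[cand$ref])
    cand <- cand[cand$diff <= tolerance_s, ]
    cand <- cand[order(cand$diff), ]
    used_d <- logical(nd); used_r <- logical(nr)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      d <- cand$det[i]; r <- cand$ref[i]
      if (!used_d[d] && !used_r[r]) {
        used_d[d] <- TRUE; used_r[r] <- TRUE; keep[i] <- TRUE
      }
    }
    cand <- cand[keep, ]
    if (nrow(cand) > 0L) {
      cand <- cand[order(cand$ref), ]
      pairs <- data.frame(
        det = cand$det, ref = cand$ref,
        insp_error_s = dt[cand$det] - rt[cand$ref],
        exp_error_s = (detected$exp_onset_idx[cand$det] -
                         reference$exp_onset_idx[cand$ref]) / fs
      )
    }
  }
  structure(
    list(
      pairs = pairs,
      missed_ref = setdiff(seq_len(nr), pairs$ref),
      false_pos_det = setdiff(seq_len(nd), pairs$det),
      n_reference = nr,
      n_matched = nrow(pairs),
      missed_pct = if (nr > 0L) 100 * (nr - nrow(pairs)) / nr else NA_real_
    ),
    class = "onset_match"
  )
}

#' @export
print.onset_match <- function(x, ...) {
  cat(sprintf(
    "<onset_match> %d/%d reference breaths matched (%.1f%% missed), %d false positives\n",
    x$n_matched, x$n_reference, x$missed_pct, length(x$false_pos_det)
  ))
  if (x$n_matched > 0L) {
    cat(sprintf("  inspiratory onset error: %+.4f +/- %.4f s\n",
                mean(x$pairs$insp_error_s), stats::sd(x$pairs$insp_error_s)))
    cat(sprintf("  expiratory onset error:  %+.4f +/- %.4f s\n",
                mean(x$pairs$exp_error_s), stats::sd(x$pairs$exp_error_s)))
  }
  invisible(x)
}

#' Absolute and relative error summaries
#'
#' Per-observation absolute error `calc - ref` and relative error
#' `100 * (calc - ref) / ref` (observations with `|ref| < 1e-9` excluded from
#' the relative summary), each reported as mean and sample SD.
#'
#' @param calc,ref Equal-length numeric vectors (n >= 2) of calculated and
#'   reference values.
#' @return A list with `absolute` and `relative` (each `mean`, `sd`, `n`).
#' @export
error_stats <- function(calc, ref) {
  if (length(calc) != length(ref)) {
    stop("consistency error: `calc` and `ref` lengths differ", call. = FALSE)
  }
  ok <- !is.na(calc) & !is.na(ref)
  calc <- calc[ok]; ref <- ref[ok]
  if (length(calc) < 2L) {
    stop("insufficient data: need at least 2 paired values", call. = FALSE)
  }
  abs_err <- calc - ref
  nz <- abs(ref) >= 1e-9
  rel_err <- 100 * abs_err[nz] / ref[nz]
  list(
    absolute = list(mean = mean(abs_err), sd = stats::sd(abs_err),
                    n = length(abs_err)),
    relative = list(
      mean = if (length(rel_err) > 0L) mean(rel_err) else NA_real_,
      sd = if (length(rel_err) > 1L) stats::sd(rel_err) else NA_real_,
      n = length(rel_err)
    )
  )
}

#' Bland-Altman agreement statistics
#'
#' Mean difference `d = y - x` and the 95% limits of agreement
#' `mean(d) +/- 1.96 sd(d)`.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("consistency error: `x` and `y` lengths differ", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  d <- y[ok] - x[ok]
  if (length(d) < 2L) {
    stop("insufficient data: need at least 2 paired values", call. = FALSE)
  }
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Ordinary least-squares fit with R^2 and error sums
#'
#' Simple linear regression of `y` on `x`, reporting the slope, intercept,
#' coefficient of determination `R^2 = 1 - SS_resid / SS_tot`, the raw
#' residual sum of squares `sse`, and its root-mean-square scale `rmse =
#' sqrt(SS_resid / (n - 2))`. Both error scales are reported because
#' published method-comparison tables sometimes print an RMSE-scale quantity
#' under the SSE heading.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, `var(x) > 0`.
#' @return List with `slope`, `intercept`, `r_squared`, `sse`, `rmse`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("insufficient data: need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate regressor: `x` has zero variance", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  resid <- fit$residuals
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r_squared = 1 - sse / sst,
       sse = sse,
       rmse = sqrt(sse / (n - 2L)),
       n = n)
}

#' Validate a detection run against reference annotations
#'
#' Matches onsets, summarizes onset errors, and (when the signals are
#' supplied) computes per-parameter absolute/relative errors, linear
#' regression and Bland-Altman agreement between the parameters calculated
#' from the detected annotation on `signal` and those from the reference
#' annotation on `ref_signal`.
#'
#' @param detected,reference [breath_annotation()]s.
#' @param signal Optional [sampled_signal()] the detection ran on.
#' @param ref_signal Optional reference [sampled_signal()] (defaults to
#'   `signal`) from which true parameters are computed.
#' @param tolerance_s Matching tolerance in seconds.
#' @param drift_correct,smooth_hz Passed to [compute_params()]; parameters
#'   are extracted identically (including the 2 Hz smoothing default) from
#'   both signals so the comparison is like for like.
#' @return A list of class `validation_report` with `n_reference`,
#'   `n_matched`, `missed_pct`, `n_false_pos`, `onset_bias_insp`,
#'   `onset_sd_insp`, `onset_bias_exp`, `onset_sd_exp`, and (with signals) a
#'   `parameters` list keyed by parameter name, each holding `absolute`,
#'   `relative`, `r_squared`, `sse`, `rmse`, `bland_altman`.
#' @export
validation_report <- function(detected, reference, signal = NULL,
                              ref_signal = NULL, tolerance_s = 0.5,
                              drift_correct = TRUE, smooth_hz = 2) {
  m <- match_onsets(detected, reference, tolerance_s)
  rep <- list(
    n_reference = m$n_reference,
    n_matched = m$n_matched,
    missed_pct = m$missed_pct,
    n_false_pos = length(m$false_pos_det),
    onset_bias_insp = mean(m$pairs$insp_error_s),
    onset_sd_insp = stats::sd(m$pairs$insp_error_s),
    onset_bias_exp = mean(m$pairs$exp_error_s),
    onset_sd_exp = stats::sd(m$pairs$exp_error_s)
  )
  if (!is.null(signal)) {
    if (is.null(ref_signal)) ref_signal <- signal
    det_par <- compute_params(signal, detected, drift_correct = drift_correct,
                              smooth_hz = smooth_hz)
    ref_par <- compute_params(ref_signal, reference,
                              drift_correct = drift_correct,
                              smooth_hz = smooth_hz)
    # Te/Ttot/Vi depend on the NEXT onset: they are only comparable when the
    # following breath is also a matched pair, otherwise the two windows
    # span different breaths (e.g. around a missed breath) and the
    # "difference" is a window artifact, not a timing error
    key <- paste(m$pairs$det, m$pairs$ref)
    next_ok <- paste(m$pairs$det + 1L, m$pairs$ref + 1L) %in% key
    rep$parameters <- list()
    for (pn in c("Ti", "Te", "Ttot", "PIF", "Vt", "Vi")) {
      calc <- det_par[[pn]][m$pairs$det]
      ref <- ref_par[[pn]][m$pairs$ref]
      ok <- !is.na(calc) & !is.na(ref)
      if (pn %in% c("Te", "Ttot", "Vi")) ok <- ok & next_ok
      if (sum(ok) < 3L) next
      es <- error_stats(calc[ok], ref[ok])
      lf <- linear_fit(ref[ok], calc[ok])
      rep$parameters[[pn]] <- list(
        absolute = es$absolute, relative = es$relative,
        r_squared = lf$r_squared, sse = lf$sse, rmse = lf$rmse,
        slope = lf$slope, intercept = lf$intercept,
        bland_altman = bland_altman(ref[ok], calc[ok]),
        n = sum(ok)
      )
    }
  }
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d/%d matched (%.1f%% missed, %d false pos)\n",
              x$n_matched, x$n_reference, x$missed_pct, x$n_false_pos))
  cat(sprintf("  inspiratory onsets: %+.4f +/- %.4f s\n",
              x$onset_bias_insp, x$onset_sd_insp))
  cat(sprintf("  expiratory onsets:  %+.4f +/- %.4f s\n",
              x$onset_bias_exp, x$onset_sd_exp))
  if (!is.null(x$parameters)) {
    for (pn in names(x$parameters)) {
      p <- x$parameters[[pn]]
      cat(sprintf("  %-4s abs %+0.4f +/- %0.4f  rel %+0.2f%% +/- %0.2f%%  R2=%0.4f\n",
                  pn, p$absolute$mean, p$absolute$sd,
                  p$relative$mean, p$relative$sd, p$r_squared))
    }
  }
  invisible(x)
}

#' Synthetic accuracy study over sampling-frequency and noise grids
#'
#' For each (fs, noise, seed) cell: generates the concatenated
#' multi-frequency validation dataset, runs flow-mode detection on the noisy
#' signal, matches the result against the generator truth and records onset
#' bias/SD and the missed-breath percentage. Optionally returns the full
#' [validation_report()] (with parameter errors against the noise-free
#' reference signal) for selected cells.
#'
#' @param fs_grid Sampling frequencies in Hz.
#' @param noise_grid Noise levels as fractions.
#' @param seeds Integer seeds; each (fs, noise) cell is run once per seed.
#' @param n_breaths_per_segment Breaths per frequency segment (100 for the
#'   full 1000-breath dataset).
#' @param tolerance_s Onset matching tolerance (s).
#' @param config A [detection_config()].
#' @param full_report_cells Optional data.frame with columns `fs`, `noise`;
#'   cells listed here also get a full parameter-level report.
#' @param ... Passed to [generate_validation_dataset()].
#' @return A list with `table` (one row per cell x seed: `fs`, `noise`,
#'   `seed`, `n_reference`, `n_matched`, `missed_pct`, `bias_insp`,
#'   `sd_insp`, `bias_exp`, `sd_exp`) and `reports` (named list of
#'   [validation_report()]s for the requested cells).
#' @export
run_synthetic_study <- function(fs_grid, noise_grid, seeds = 1L,
                                n_breaths_per_segment = 100,
                                tolerance_s = 0.5,
                                config = detection_config(),
                                full_report_cells = NULL, ...) {
  rows <- list()
  reports <- list()
  for (fs in fs_grid) {
    for (noise in noise_grid) {
      for (seed in seeds) {
        ds <- generate_validation_dataset(
          fs = fs, noise_level = noise, seed = seed,
          n_breaths_per_segment = n_breaths_per_segment, ...
        )
        det <- detect_breaths(ds$noisy, config)
        want_full <- !is.null(full_report_cells) &&
          any(full_report_cells$fs == fs & full_report_cells$noise == noise)
        rep <- validation_report(
          det, ds$truth,
          signal = if (want_full) ds$noisy else NULL,
          ref_signal = if (want_full) ds$reference else NULL,
          tolerance_s = tolerance_s,
          drift_correct = config$drift_correct
        )
        rows[[length(rows) + 1L]] <- data.frame(
          fs = fs, noise = noise, seed = seed,
          n_reference = rep$n_reference, n_matched = rep$n_matched,
          missed_pct = rep$missed_pct,
          bias_insp = rep$onset_bias_insp, sd_insp = rep$onset_sd_insp,
          bias_exp = rep$onset_bias_exp, sd_exp = rep$onset_sd_exp
        )
        if (want_full) {
          reports[[sprintf("fs%g_noise%g_seed%d", fs, noise, seed)]] <- rep
        }
      }
    }
  }
  list(table = do.call(rbind, rows), reports = reports)
}

#' Plot a synthetic-study table
#'
#' Base-graphics summary of onset-error SD against noise level, one line per
#' sampling frequency (the qualitative pattern: error grows with noise,
#' shrinks with sampling frequency).
#'
#' @param table The `table` element of [run_synthetic_study()] output.
#' @param what Column to plot (default `"sd_insp"`).
#' @return Invisibly, the aggregated data used for the plot.
#' @export
plot_study <- function(table, what = "sd_insp") {
  agg <- stats::aggregate(table[[what]],
                          by = list(fs = table$fs, noise = table$noise), mean)
  names(agg)[3L] <- what
  fss <- sort(unique(agg$fs))
  cols <- grDevices::hcl.colors(length(fss), "viridis")
  plot(NULL, xlim = range(agg$noise), ylim = range(agg[[what]]),
       xlab = "noise level (fraction)", ylab = paste(what, "(s)"),
       main = "Onset-error variability")
  for (i in seq_along(fss)) {
    sub <- agg[agg$fs == fss[i], ]
    graphics::lines(sub$noise, sub[[what]], col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("topleft", legend = paste(fss, "Hz"), col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(agg)
}
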