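#' Per-breath respiratory parameters
#'
#' Computes, for each annotated breath: inspiratory time `Ti` (seconds,
#' inspiratory to expiratory onset), expiratory time `Te` (expiratory onset
#' to the next inspiratory onset), `Ttot = Ti + Te`, peak inspiratory flow
#' `PIF` (L/s), tidal volume `Vt` (L, the per-breath integrated volume read
#' at the expiratory onset), minute ventilation `Vi = Vt * 60 / Ttot`
#' (L/min), and
#' optionally the nadir epiglottic pressure over inspiration (cmH2O).
#'
#' With `drift_correct = TRUE` (the default) the integrated volume has the
#' straight line through its two per-breath endpoints subtracted before `Vt`
#' is read off, and `PIF` is the maximum of the correspondingly corrected
#' flow (flow minus the per-breath mean); for physiological breaths with
#' near-zero net volume this is indistinguishable from the raw definitions,
#' while under baseline drift it keeps `Vt`/`PIF` anchored to the breath
#' rather than the drift.
#'
#' The last breath has no following inspiratory onset, so its `Te`, `Ttot`
#' and `Vi` are `NA` (its integration window extends to the end of the
#' record); a `tail` column marks it.
#'
#' @param flow A [sampled_signal()] with `kind = "flow"`.
#' @param annotation A [breath_annotation()] on the same time base.
#' @param pepi Optional [sampled_signal()] with `kind = "pressure"`, same fs
#'   and length, for `nadir_pepi`.
#' @param drift_correct Apply the per-breath two-point drift correction
#'   (default TRUE).
#' @param smooth_hz Optional zero-phase low-pass cut-off (Hz) applied to the
#'   flow before parameters are extracted. `NULL` (default) uses the raw
#'   samples; validation against noisy recordings uses 2 Hz on both the test
#'   and reference signals so that sample-level noise does not bias the
#'   extreme-value statistic `PIF`.
#' @param invert_flow Set TRUE for inverted transducers (inspiration
#'   negative); the sign is flipped before computation.
#' @param nadir_over Window for `nadir_pepi`: `"inspiration"` (default) or
#'   `"breath"`.
#' @return A data.frame of class `respiratory_params`, one row per breath,
#'   with columns `breath`, `Ti`, `Te`, `Ttot`, `PIF`, `Vt`, `Vi`,
#'   (`nadir_pepi`), `tail`.
#' @export
#' @examples
#' fl <- sampled_signal(c(rep(0.5, 500), rep(-0.5, 500), rep(0.5, 500),
#'                        rep(-0.5, 501)), fs = 250)
#' ann <- breath_annotation(c(0L, 1000L), c(500L, 1500L), fs = 250)
#' compute_params(fl, ann)
compute_params <- function(flow, annotation, pepi = NULL,
                           drift_correct = TRUE, smooth_hz = NULL,
                           invert_flow = FALSE,
                           nadir_over = c("inspiration", "breath")) {
  nadir_over <- match.arg(nadir_over)
  validate_signal(flow)
  if (!is.null(smooth_hz)) {
    flow$values <- lowpass_zerophase(flow$values, smooth_hz, flow$fs)
  }
  if (flow$kind != "flow") {
    stop("config error: `flow` must have kind = \"flow\"", call. = FALSE)
  }
  if (!isTRUE(all.equal(annotation$fs, flow$fs))) {
    stop("consistency error: annotation and flow sampling rates differ",
         call. = FALSE)
  }
  n <- length(flow$values)
  k <- length(annotation$insp_onset_idx)
  if (k == 0L) {
    return(structure(
      data.frame(breath = integer(0), Ti = numeric(0), Te = numeric(0),
                 Ttot = numeric(0), PIF = numeric(0), Vt = numeric(0),
                 Vi = numeric(0), tail = logical(0)),
      class = c("respiratory_params", "data.frame")
    ))
  }
  if (max(annotation$exp_onset_idx) > n - 1L) {
    stop("consistency error: annotation indices beyond the flow signal",
         call. = FALSE)
  }
  if (invert_flow) flow$values <- -flow$values
  fs <- flow$fs
  insp <- annotation$insp_onset_idx
  expo <- annotation$exp_onset_idx
  nxt <- c(insp[-1L], NA_integer_)
  win_end <- ifelse(is.na(nxt), n - 1L, nxt)

  Ti <- (expo - insp) / fs
  Te <- (nxt - expo) / fs
  Ttot <- Ti + Te
  PIF <- Vt <- numeric(k)
  for (i in seq_len(k)) {
    v <- cumulative_volume(flow, insp[i], win_end[i])
    m <- length(v)
    offset <- 0
    if (drift_correct) {
      offset <- v[m] / ((m - 1) / fs) # per-breath mean flow
      v <- v - v[m] * (seq_len(m) - 1) / (m - 1)
    }
    e_rel <- expo[i] - insp[i] + 1L
    Vt[i] <- v[e_rel]
    PIF[i] <- max(flow$values[(insp[i] + 1L):(expo[i] + 1L)]) - offset
  }
  Vi <- Vt * 60 / Ttot
  out <- data.frame(breath = seq_len(k), Ti = Ti, Te = Te, Ttot = Ttot,
                    PIF = PIF, Vt = Vt, Vi = Vi,
                    tail = c(rep(FALSE, k - 1L), TRUE))
  if (!is.null(pepi)) {
    validate_signal(pepi)
    if (!isTRUE(all.equal(pepi$fs, flow$fs)) ||
        length(pepi$values) != length(flow$values)) {
      stop("consistency error: `pepi` must match the flow signal in fs and length",
           call. = FALSE)
    }
    out$nadir_pepi <- vapply(seq_len(k), function(i) {
      to <- if (nadir_over == "inspiration") expo[i] else win_end[i]
      min(pepi$values[(insp[i] + 1L):(to + 1L)])
    }, numeric(1))
  }
  structure(out, class = c("respiratory_params", "data.frame"))
}

#' Summarize respiratory parameters
#'
#' Mean, sample standard deviation (n - 1 denominator) and n per parameter,
#' ignoring `NA`s (e.g. the tail breath's `Te`/`Ttot`/`Vi`).
#'
#' @param params A `respiratory_params` data.frame from [compute_params()].
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_params <- function(params) {
  cols <- intersect(c("Ti", "Te", "Ttot", "PIF", "Vt", "Vi", "nadir_pepi"),
                    names(params))
  if (nrow(params) == 0L) {
    return(data.frame(parameter = character(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0)))
  }
  do.call(rbind, lapply(cols, function(cn) {
    x <- params[[cn]]
    x <- x[!is.na(x)]
    data.frame(parameter = cn, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n = length(x))
  }))
}
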