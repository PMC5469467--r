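#' Read a signal from delimited text
#'
#' The signal schema is a CSV with header `time_s,value`, one row per sample,
#' preceded by comment lines of the form `# fs=250`, `# kind=flow`,
#' `# units=L/s`. The time column must be monotone and consistent with `fs`
#' to within 1e-6 s.
#'
#' @param path File path.
#' @param fs Optional override for the sampling frequency (required if the
#'   file has no `# fs=` header).
#' @param kind Optional override for the signal kind.
#' @return A [sampled_signal()].
#' @export
read_signal <- function(path, fs = NULL, kind = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(hdr)
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) {
    stop("config error: sampling frequency not in file header; pass `fs`",
         call. = FALSE)
  }
  if (is.null(kind)) kind <- if (!is.null(meta$kind)) meta$kind else "flow"
  if (identical(kind, "pepi")) kind <- "pressure"
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("format error: expected columns `time_s,value`", call. = FALSE)
  }
  if (nrow(df) >= 2L) {
    dt <- diff(df$time_s)
    bad <- which(dt <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("format error: non-monotone time at row %d", bad[1L] + 1L),
           call. = FALSE)
    }
    if (max(abs(dt - 1 / fs)) > 1e-6) {
      stop("format error: time column inconsistent with fs", call. = FALSE)
    }
  }
  sampled_signal(df$value, fs = fs, kind = kind, t0 = df$time_s[1L])
}

parse_meta <- function(hdr) {
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", h))[[1L]]
    if (length(m) == 3L) {
      key <- m[2L]; val <- m[3L]
      meta[[key]] <- if (key == "fs") as.numeric(val) else val
    }
  }
  meta
}

#' Write a signal to delimited text
#'
#' @param signal A [sampled_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  validate_signal(signal)
  units <- switch(signal$kind, flow = "L/s", pressure = "cmH2O", volume = "L")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", signal$fs),
    sprintf("# kind=%s", signal$kind),
    sprintf("# units=%s", units),
    "time_s,value"
  ), con)
  t <- signal$t0 + (seq_along(signal$values) - 1L) / signal$fs
  writeLines(sprintf("%.9f,%.12g", t, signal$values), con)
  invisible(path)
}

#' Write a breath annotation to delimited text
#'
#' Annotation schema: CSV with header `breath,insp_onset_s,exp_onset_s`,
#' times in seconds from record start with 6+ decimals so indices round-trip
#' exactly at 1/fs resolution; a `# fs=` comment line records the sampling
#' frequency.
#'
#' @param annotation A [breath_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", annotation$fs),
               "breath,insp_onset_s,exp_onset_s"), con)
  k <- length(annotation$insp_onset_idx)
  if (k > 0L) {
    writeLines(sprintf("%d,%.9f,%.9f", seq_len(k),
                       annotation$insp_onset_idx / annotation$fs,
                       annotation$exp_onset_idx / annotation$fs), con)
  }
  invisible(path)
}

#' Read a breath annotation from delimited text
#'
#' Indices are recovered by rounding `time * fs`; a deviation of more than
#' 1e-3 samples from an integral index triggers a warning (likely fs
#' mismatch).
#'
#' @param path File path.
#' @param fs Sampling frequency; defaults to the file's `# fs=` header.
#' @return A [breath_annotation()].
#' @export
read_annotation <- function(path, fs = NULL) {
  lines <- readLines(path)
  meta <- parse_meta(grep("^#", lines, value = TRUE))
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) {
    stop("config error: sampling frequency not in file header; pass `fs`",
         call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("breath", "insp_onset_s", "exp_onset_s") %in% names(df))) {
    stop("format error: expected columns `breath,insp_onset_s,exp_onset_s`",
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(breath_annotation(integer(0), integer(0), fs))
  insp_f <- df$insp_onset_s * fs
  exp_f <- df$exp_onset_s * fs
  if (max(abs(insp_f - round(insp_f)), abs(exp_f - round(exp_f))) > 1e-3) {
    warning("annotation times are not integral sample indices at this fs",
            call. = FALSE)
  }
  breath_annotation(round(insp_f), round(exp_f), fs)
}

#' Write a validation report (or any list) as JSON
#'
#' @param report A list, e.g. a [validation_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
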