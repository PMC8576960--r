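#' Construct a single-lead ECG record
#'
#' An `ecg_record` bundles a raw amplitude series (lead II semantics, mV)
#' with its sampling frequency and provenance. All downstream analysis —
#' R-peak detection, P-wave delineation, HRV — starts from this container.
#'
#' @param samples Numeric vector of amplitudes in mV; must be non-empty and
#'   finite.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param subject_id Subject identifier (single string).
#' @param label Optional class tag, one of `"PAF"` or `"normal"`, or `NA`.
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `subject_id`, `label`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 256)), fs = 128,
#'                   subject_id = "demo")
#' rec
#' @export
ecg_record <- function(samples, fs, subject_id = "unknown", label = NA_character_) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stopf("'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stopf("'samples' must be finite")
  if (!is.na(label) && !label %in% c("PAF", "normal"))
    stopf("'label' must be \"PAF\", \"normal\" or NA")
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id)[1L],
                 label = as.character(label)[1L]),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples at %g Hz (%.1f s)%s\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.na(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Construct an RR-interval series
#'
#' @param intervals Positive inter-beat intervals in milliseconds.
#' @param beat_times Optional strictly increasing beat times in seconds; when
#'   derived from R-peaks there is one more beat time than interval. If
#'   omitted, beat times are reconstructed by cumulating the intervals from 0.
#' @return An object of class `rr_series` with elements `intervals` (ms) and
#'   `beat_times` (s).
#' @export
rr_series <- function(intervals, beat_times = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L || !all(is.finite(intervals)))
    stopf("'intervals' must be non-empty and finite")
  if (any(intervals <= 0))
    stopf("all RR intervals must be positive")
  if (is.null(beat_times)) {
    beat_times <- c(0, cumsum(intervals)) / 1000
  } else {
    beat_times <- as.numeric(beat_times)
    if (any(diff(beat_times) <= 0))
      stopf("'beat_times' must be strictly increasing")
    if (!length(beat_times) %in% (length(intervals) + 0:1))
      stopf("'beat_times' length must equal length(intervals) or length(intervals) + 1")
  }
  structure(list(intervals = intervals, beat_times = beat_times),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d intervals, mean %.1f ms, span %.1f s\n",
              length(x$intervals), mean(x$intervals),
              diff(range(x$beat_times))))
  invisible(x)
}

#' Convert R-peak sample indices to an RR-interval series
#'
#' @param peaks Strictly increasing R-peak sample indices.
#' @param fs Sampling frequency in Hz.
#' @return An [rr_series()] with `length(peaks) - 1` intervals in ms and
#'   `length(peaks)` beat times in seconds.
#' @examples
#' rr_from_peaks(c(0, 128, 256), fs = 128)$intervals  # 1000 1000
#' @export
rr_from_peaks <- function(peaks, fs) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2L)
    stopf("need at least 2 peaks to form an RR interval")
  if (any(diff(peaks) <= 0))
    stopf("'peaks' must be strictly increasing")
  rr_series(diff(peaks) / fs * 1000, beat_times = peaks / fs)
}

#' Read and write ECG sample files
#'
#' The on-disk format is one amplitude sample (mV) per line, preceded by
#' `#`-prefixed header lines carrying the sampling frequency and metadata,
#' e.g. `# fs=128`, `# subject_id=p01`, `# label=PAF`. This dialect
#' round-trips bit-exactly through [write_ecg()] / [read_ecg()].
#'
#' @param path File path.
#' @return `read_ecg()` returns an [ecg_record()]; `write_ecg()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_ecg(ecg_record(c(0, 0.5, 1), fs = 128, subject_id = "s1"), f)
#' read_ecg(f)
#' @export
read_ecg <- function(path) {
  if (!file.exists(path))
    stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stopf("parse error: empty file '%s'", path)
  hdr <- grepl("^#", lines)
  meta <- parse_header(lines[hdr])
  if (is.null(meta$fs))
    stopf("format error: no '# fs=<Hz>' header in '%s'", path)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs) || fs <= 0)
    stopf("format error: invalid sampling rate '%s'", meta$fs)
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (length(body) == 0L)
    stopf("parse error: no samples in '%s'", path)
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples))
    stopf("parse error: non-numeric sample at line %d",
          which(!hdr & nzchar(trimws(lines)))[which(is.na(samples))[1L]])
  ecg_record(samples, fs = fs,
             subject_id = meta$subject_id %||% "unknown",
             label = meta$label %||% NA_character_)
}

#' @param record An [ecg_record()].
#' @rdname read_ecg
#' @export
write_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  hdr <- c(sprintf("# fs=%s", format(record$fs, digits = 17)),
           sprintf("# subject_id=%s", record$subject_id))
  if (!is.na(record$label))
    hdr <- c(hdr, sprintf("# label=%s", record$label))
  writeLines(c(hdr, format_exact(record$samples)), path)
  invisible(path)
}

#' Read and write RR-interval text files
#'
#' One interval in milliseconds per line; `#`-prefixed header lines are
#' ignored (and may carry `subject_id`).
#'
#' @param path File path.
#' @return `read_rr()` returns an [rr_series()]; `write_rr()` returns `path`
#'   invisibly.
#' @export
read_rr <- function(path) {
  if (!file.exists(path))
    stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    stopf("parse error: no intervals in '%s'", path)
  x <- suppressWarnings(as.numeric(body))
  if (anyNA(x))
    stopf("parse error: non-numeric interval in '%s'", path)
  rr_series(x)
}

#' @param rr An [rr_series()].
#' @rdname read_rr
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(format_exact(rr$intervals), path)
  invisible(path)
}

# full-precision decimal text that survives as.numeric round-trip
format_exact <- function(x) {
  formatC(x, format = "g", digits = 17)
}

parse_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L)
      out[[m[2L]]] <- trimws(m[3L])
  }
  out
}
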