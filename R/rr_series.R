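#' RR-interval series
#'
#' Container for a beat-to-beat interval series: the raw HRV signal. Beat
#' times are seconds since record start; RR intervals are the successive
#' differences in milliseconds, so `rr_ms[i]` is the interval ending at
#' `beat_times[i + 1]`.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param rr_ms Optional numeric vector of RR intervals in milliseconds,
#'   length `length(beat_times) - 1`. Computed from `beat_times` when omitted.
#' @param record_id Opaque record label.
#' @return An object of class `rr_series` with fields `beat_times`, `rr_ms`
#'   and `record_id`.
#' @examples
#' rr_series(c(0, 0.8, 1.6, 2.4))
#' @export
rr_series <- function(beat_times, rr_ms = NULL, record_id = "record") {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) {
    stop("an RR series needs at least two beats", call. = FALSE)
  }
  if (any(!is.finite(beat_times)) || any(diff(beat_times) <= 0)) {
    stop("beat_times must be finite and strictly increasing", call. = FALSE)
  }
  if (is.null(rr_ms)) {
    rr_ms <- diff(beat_times) * 1000
  }
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) != length(beat_times) - 1) {
    stop("length(rr_ms) must be length(beat_times) - 1", call. = FALSE)
  }
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("all RR intervals must be finite and positive", call. = FALSE)
  }
  structure(
    list(beat_times = beat_times, rr_ms = rr_ms, record_id = as.character(record_id)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series '%s': %d beats over %.1f s, mean RR %.1f ms>\n",
    x$record_id, length(x$beat_times), diff(range(x$beat_times)), mean(x$rr_ms)
  ))
  invisible(x)
}

#' Per-minute apnea annotations
#'
#' One label per whole minute of a record; minute `m` covers the half-open
#' interval `[60 m, 60 (m + 1))` seconds.
#'
#' @param labels Character vector with elements `"apnea"` or `"normal"`.
#' @return A validated character vector of class `minute_annotations`.
#' @export
minute_annotations <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) {
    stop("annotation sequence is empty", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("apnea", "normal"))
  if (length(bad)) {
    stop("unknown annotation labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(labels, class = "minute_annotations")
}

#' Read an RR series from CSV
#'
#' Expects the two-column convention `time_s,rr_ms`, one row per beat: the
#' beat time in seconds and the interval (ms) ending at that beat. The first
#' row's `rr_ms` may be empty/NA (no interval ends at the first beat).
#'
#' @param path CSV file path.
#' @param record_id Record label; defaults to the file name without extension.
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path, record_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "rr_ms") %in% names(df))) {
    stop("RR CSV must have columns time_s, rr_ms: ", path, call. = FALSE)
  }
  id <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  rr <- df$rr_ms[-1]
  if (anyNA(rr)) {
    stop("missing rr_ms after the first row in ", path, call. = FALSE)
  }
  rr_series(df$time_s, rr, record_id = id)
}

#' Write an RR series to CSV
#'
#' Inverse of [read_rr_csv()]: `time_s,rr_ms` with an empty interval on the
#' first beat row.
#'
#' @param rr An [rr_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(time_s = rr$beat_times, rr_ms = c(NA, rr$rr_ms))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
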