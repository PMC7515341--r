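#' Remove ectopic-beat artifacts with a running-median filter
#'
#' Automatic beat detection leaves occasional spurious intervals (missed or
#' doubled beats). Any RR value deviating from the running median of its
#' window by more than `rel_threshold` times that median is replaced by the
#' median. Beat times are rebuilt by cumulative summation from the first beat
#' so the series stays self-consistent; the series length never changes and
#' the filter is idempotent on already-clean series.
#'
#' @param rr An [rr_series()].
#' @param window Odd window length in beats (>= 3).
#' @param rel_threshold Relative deviation tolerance, in (0, 1); 0.2 means a
#'   beat is an artifact when it deviates by more than 20% of the local median.
#' @return A cleaned [rr_series()] of identical length.
#' @examples
#' rr <- rr_series(c(0, 0.8, 1.61, 3.6, 4.4, 5.2, 6.0))
#' remove_artifacts(rr)
#' @export
remove_artifacts <- function(rr, window = 5, rel_threshold = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop("rel_threshold must be in (0, 1)", call. = FALSE)
  }
  x <- rr$rr_ms
  if (length(x) < window) {
    stop("series shorter than the median-filter window: insufficient data", call. = FALSE)
  }
  med <- stats::runmed(x, k = window, endrule = "median")
  bad <- abs(x - med) > rel_threshold * med
  x[bad] <- med[bad]
  beat_times <- rr$beat_times[1] + c(0, cumsum(x) / 1000)
  rr_series(beat_times, x, record_id = rr$record_id)
}

#' Tile a record into labeled 5-minute windows
#'
#' The record is cut into consecutive, non-overlapping 5-minute windows
#' aligned to minute boundaries (window w spans `[300 w, 300 (w + 1))`
#' seconds). A window from a class-A record (an OSA patient) with at least
#' one apnea-annotated minute becomes `A-OSA`; with none, `A-N`. A window
#' from a class-C record (control) with no apnea minutes becomes `C-N`;
#' class-C windows containing any apnea minute are discarded, as is a
#' trailing partial window.
#'
#' @param rr An [rr_series()]; beat times in record seconds.
#' @param ann A [minute_annotations()] covering the record.
#' @param record_class `"A"` (apnea patient) or `"C"` (control).
#' @param margin_s Seconds of context kept on either side of each window so
#'   that the spline in [interpolate_resample()] interpolates rather than
#'   extrapolates at window edges.
#' @return A list of raw-window objects (class `rr_window`), each with
#'   `beat_times`, `rr_ms`, `start_s`, `label` and `record_id`.
#' @export
segment_and_label <- function(rr, ann, record_class = c("A", "C"), margin_s = 10) {
  stopifnot(inherits(rr, "rr_series"))
  record_class <- match.arg(record_class)
  if (length(ann) == 0) {
    stop("annotation sequence is empty", call. = FALSE)
  }
  ann <- minute_annotations(ann)
  n_windows <- length(ann) %/% 5
  out <- list()
  for (w in seq_len(n_windows) - 1L) {
    start <- 300 * w
    minutes <- ann[(5 * w + 1):(5 * w + 5)]
    n_apnea <- sum(minutes == "apnea")
    label <- if (record_class == "A") {
      if (n_apnea >= 1) "A-OSA" else "A-N"
    } else {
      if (n_apnea >= 1) NA_character_ else "C-N"
    }
    if (is.na(label)) next
    keep <- rr$beat_times >= start - margin_s & rr$beat_times <= start + 300 + margin_s
    idx <- which(keep)
    if (length(idx) < 2) next
    out[[length(out) + 1]] <- structure(
      list(
        beat_times = rr$beat_times[idx],
        rr_ms = rr$rr_ms[idx[-1] - 1],
        start_s = start,
        label = label,
        record_id = rr$record_id
      ),
      class = "rr_window"
    )
  }
  out
}

#' A uniformly resampled 5-minute HRV segment
#'
#' @param tachogram Numeric vector of RR values (ms) on the uniform grid.
#' @param start_s Window start in record seconds.
#' @param label Group label (`A-OSA`, `A-N`, `C-N`, or a synthetic analogue).
#' @param record_id Source record label.
#' @param fs Resampling rate in Hz.
#' @param duration_s Window duration in seconds.
#' @return An object of class `hrv_segment`.
#' @export
hrv_segment <- function(tachogram, start_s = 0, label = "unknown",
                        record_id = "record", fs = 4, duration_s = 300) {
  tachogram <- as.numeric(tachogram)
  n_expected <- as.integer(round(duration_s * fs))
  if (length(tachogram) != n_expected) {
    stop(sprintf("tachogram must have %d samples (%g s at %g Hz)", n_expected, duration_s, fs),
      call. = FALSE
    )
  }
  if (any(!is.finite(tachogram)) || any(tachogram <= 0)) {
    stop("tachogram values must be finite and positive", call. = FALSE)
  }
  structure(
    list(
      tachogram = tachogram, start_s = start_s, label = label,
      record_id = record_id, fs = fs, duration_s = duration_s
    ),
    class = "hrv_segment"
  )
}

#' @export
print.hrv_segment <- function(x, ...) {
  cat(sprintf(
    "<hrv_segment %s @ %gs [%s]: %d samples at %g Hz, mean RR %.1f ms>\n",
    x$record_id, x$start_s, x$label, length(x$tachogram), x$fs, mean(x$tachogram)
  ))
  invisible(x)
}

#' Cubic-spline interpolation and uniform resampling of a raw window
#'
#' The RR interval series is irregularly sampled (one value per beat), while
#' AR spectral estimation needs a uniform grid. A cubic spline through
#' (beat time, RR) - each interval attached to the beat that ends it - is
#' evaluated on the uniform grid covering `[start_s, start_s + 300 s)`. The
#' interpolant passes exactly through the beat-time knots.
#'
#' @param win An `rr_window` from [segment_and_label()], or anything with
#'   `beat_times`, `rr_ms`, `start_s`, `label`, `record_id` fields.
#' @param fs Resampling rate in Hz (4 Hz gives the canonical 1200 samples).
#' @return An [hrv_segment()].
#' @export
interpolate_resample <- function(win, fs = 4) {
  t_knots <- win$beat_times[-1]
  v_knots <- win$rr_ms
  if (length(t_knots) < 4) {
    stop("unusable segment: fewer than 4 beats for cubic-spline interpolation", call. = FALSE)
  }
  grid <- win$start_s + seq(0, by = 1 / fs, length.out = as.integer(300 * fs))
  f <- stats::splinefun(t_knots, v_knots, method = "fmm")
  y <- f(grid)
  if (any(!is.finite(y))) {
    stop("non-finite spline output in segment at ", win$start_s, " s", call. = FALSE)
  }
  if (any(y <= 0)) {
    stop("non-positive tachogram after interpolation at ", win$start_s, " s", call. = FALSE)
  }
  hrv_segment(y,
    start_s = win$start_s, label = win$label %||% "unknown",
    record_id = win$record_id %||% "record", fs = fs
  )
}
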