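#' Read a WFDB record header and signal
#'
#' Minimal reader for PhysioNet WFDB records: parses the `.hea` header and
#' reads the companion `.dat` signal file. Signal formats 16 (16-bit
#' little-endian) and 212 (packed 12-bit pairs) are supported, which covers
#' the apnea ECG recordings' convention. Values are converted to physical
#' units via `(adc - baseline) / gain`.
#'
#' @param record Path prefix of the record (no extension); `record.hea` and
#'   the `.dat` file it names must exist.
#' @return A list: `record_id`, `fs` (Hz), `n_samples`, `signal` (numeric
#'   matrix, one column per channel) and `description` per channel.
#' @export
read_wfdb_record <- function(record) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(head_fields[2])
  fs <- if (length(head_fields) >= 3) as.numeric(sub("/.*", "", head_fields[3])) else 250
  n_samples <- if (length(head_fields) >= 4) as.integer(head_fields[4]) else NA_integer_
  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else {
      0
    }
    list(
      file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
      gain = if (is.na(gain) || gain == 0) 200 else gain, baseline = baseline,
      description = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    )
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_file <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat_file)) stop("signal file not found: ", dat_file, call. = FALSE)
  fmt <- sigs[[1]]$format
  raw_bytes <- readBin(dat_file, "raw", n = file.info(dat_file)$size)
  adc <- switch(as.character(fmt),
    "16" = {
      v <- readBin(raw_bytes, "integer",
        n = length(raw_bytes) %/% 2,
        size = 2, signed = TRUE, endian = "little"
      )
      matrix(v, ncol = n_sig, byrow = TRUE)
    },
    "212" = {
      b <- as.integer(raw_bytes)
      n_tri <- length(b) %/% 3
      b1 <- b[seq(1, by = 3, length.out = n_tri)]
      b2 <- b[seq(2, by = 3, length.out = n_tri)]
      b3 <- b[seq(3, by = 3, length.out = n_tri)]
      s1 <- b1 + bitwAnd(b2, 15L) * 256L
      s2 <- b3 + bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      matrix(as.vector(rbind(s1, s2)), ncol = n_sig, byrow = TRUE)
    },
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE)
  )
  if (!is.na(n_samples) && nrow(adc) > n_samples) {
    adc <- adc[seq_len(n_samples), , drop = FALSE]
  }
  physical <- sapply(seq_len(n_sig), function(j) {
    (adc[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain
  })
  list(
    record_id = basename(record), fs = fs, n_samples = nrow(adc),
    signal = as.matrix(physical),
    description = vapply(sigs, function(s) s$description, "")
  )
}

#' Read per-minute apnea annotations from a WFDB annotation file
#'
#' Parses the standard MIT annotation byte-pair stream: each word carries a
#' 6-bit type code and a 10-bit sample increment; `SKIP` (59) carries a
#' 4-byte operand and `NUM`/`SUB`/`CHN`/`AUX` (60-63) modifier words are
#' skipped. Per the apnea annotation convention, type code 8 (`A`) marks an
#' apnea minute and type code 1 (`N`) a normal minute; one annotation is
#' expected per minute.
#'
#' @param path Annotation file (e.g. `record.apn`).
#' @param fs Sampling rate of the annotated record in Hz.
#' @return A [minute_annotations()] vector ordered by minute.
#' @export
read_wfdb_apnea_annotations <- function(path, fs = 100) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  bytes <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  i <- 1L
  t_sample <- 0
  times <- numeric(0)
  codes <- integer(0)
  while (i + 1L <= length(bytes)) {
    word <- bytes[i] + bytes[i + 1L] * 256L
    code <- bitwShiftR(word, 10L)
    incr <- bitwAnd(word, 1023L)
    i <- i + 2L
    if (code == 0L && incr == 0L) break # end of file
    if (code == 59L) { # SKIP: 4-byte long operand follows (PDP-11 word order)
      if (i + 3L > length(bytes)) break
      high <- bytes[i] + bytes[i + 1L] * 256L
      low <- bytes[i + 2L] + bytes[i + 3L] * 256L
      t_sample <- t_sample + high * 65536 + low
      i <- i + 4L
      next
    }
    if (code >= 60L && code <= 62L) next # NUM / SUB / CHN modifiers
    if (code == 63L) { # AUX: incr = byte count, padded to even
      i <- i + incr + (incr %% 2L)
      next
    }
    t_sample <- t_sample + incr
    times <- c(times, t_sample)
    codes <- c(codes, code)
  }
  keep <- codes %in% c(1L, 8L)
  if (!any(keep)) stop("no apnea/normal annotations found in ", path, call. = FALSE)
  ord <- order(times[keep])
  minute_annotations(ifelse(codes[keep][ord] == 8L, "apnea", "normal"))
}

#' Detect beats in a single-channel ECG
#'
#' Pluggable interface for turning an ECG trace into beat times. The
#' `detector` argument takes any `function(signal, fs)` returning beat times
#' in seconds, so an external QRS detector can be dropped in. The bundled
#' default is a deliberately simple amplitude detector (moving-average
#' detrend, threshold at 60% of the 99.9th amplitude percentile, 250 ms
#' refractory period) adequate for clean synthetic traces; for clinical ECG
#' a validated QRS detector should be supplied instead.
#'
#' @param signal Numeric vector, one ECG channel.
#' @param fs Sampling rate in Hz.
#' @param detector Optional replacement detector function.
#' @return An [rr_series()] of the detected beats.
#' @export
rr_from_ecg <- function(signal, fs, detector = NULL) {
  beats <- if (is.null(detector)) {
    simple_peak_detector(signal, fs)
  } else {
    detector(signal, fs)
  }
  if (length(beats) < 2) stop("fewer than two beats detected", call. = FALSE)
  rr_series(beats, record_id = "ecg")
}

simple_peak_detector <- function(signal, fs) {
  w <- max(1L, as.integer(round(0.6 * fs)))
  baseline <- stats::filter(signal, rep(1 / w, w), sides = 2)
  x <- signal - ifelse(is.na(baseline), mean(signal), baseline)
  thr <- 0.6 * stats::quantile(abs(x), 0.999, names = FALSE)
  above <- which(x > thr)
  if (!length(above)) {
    return(numeric(0))
  }
  refr <- as.integer(round(0.25 * fs))
  peaks <- integer(0)
  run_start <- above[1]
  prev <- above[1]
  flush <- function(s, e) s - 1L + which.max(x[s:e])
  for (i in above[-1]) {
    if (i - prev > refr) {
      peaks <- c(peaks, flush(run_start, prev))
      run_start <- i
    }
    prev <- i
  }
  peaks <- c(peaks, flush(run_start, prev))
  (peaks - 1L) / fs
}
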