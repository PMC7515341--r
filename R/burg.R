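#' Fit an autoregressive model with the Burg lattice algorithm
#'
#' Estimates the coefficients of the all-pole model
#' `x(t) = -sum_k a_k x(t - k) + u(t)`, with `u` white noise of variance
#' `delta2`, by minimising the summed forward and backward prediction-error
#' power stage by stage on the lattice. Burg estimation works directly on
#' the samples - no autocorrelation sequence is formed - which is what makes
#' it reliable on 5-minute HRV windows of a few hundred points.
#'
#' The signal mean is removed before fitting. The returned coefficients
#' follow the sign convention above, so the prediction-error filter is
#' `A(z) = 1 + sum_k a_k z^-k`.
#'
#' @param x Numeric vector, length > `2 * order`, not constant.
#' @param order AR order p >= 1 (16 is the standard choice for 4 Hz HRV).
#' @param sample_rate Sampling rate in Hz, carried along for [ar_psd()].
#' @return An object of class `ar_model`: `order`, `a` (coefficients a_1..a_p),
#'   `var` (innovation variance delta^2), `reflection` (lattice reflection
#'   coefficients, all |k| < 1 on non-degenerate input) and `sample_rate`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 2048))
#' burg_fit(x, 1)$a # close to -0.5
#' @export
burg_fit <- function(x, order, sample_rate = 4) {
  x <- as.numeric(x)
  order <- as.integer(order)
  if (order < 1) {
    stop("AR order must be >= 1", call. = FALSE)
  }
  n <- length(x)
  if (n <= 2 * order) {
    stop("signal too short for AR order ", order, " (need > 2p samples)", call. = FALSE)
  }
  x <- x - mean(x)
  if (all(x == 0) || stats::var(x) == 0) {
    stop("degenerate segment: constant (zero-variance) signal", call. = FALSE)
  }
  f <- x
  b <- x
  a <- numeric(0)
  refl <- numeric(order)
  err <- mean(x^2)
  for (m in seq_len(order)) {
    ff <- f[(m + 1):n]
    bb <- b[m:(n - 1)]
    denom <- sum(ff^2) + sum(bb^2)
    if (denom == 0) {
      stop("degenerate segment: prediction error vanished at stage ", m, call. = FALSE)
    }
    k <- -2 * sum(ff * bb) / denom
    a <- c(a + k * rev(a), k)
    f_new <- ff + k * bb
    b_new <- bb + k * ff
    f[(m + 1):n] <- f_new
    b[(m + 1):n] <- b_new
    err <- err * (1 - k^2)
    refl[m] <- k
  }
  structure(
    list(order = order, a = a, var = err, reflection = refl, sample_rate = sample_rate),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf(
    "<ar_model p=%d, fs=%g Hz, innovation variance %.4g>\n",
    x$order, x$sample_rate, x$var
  ))
  invisible(x)
}

#' Parametric AR power spectrum
#'
#' Evaluates `S(f) = delta^2 / |1 + sum_k a_k exp(-i 2 pi f k / fs)|^2`
#' pointwise on a frequency grid. With all coefficients zero the spectrum is
#' flat at `delta^2`; the function is even in `f` and non-negative
#' everywhere below the Nyquist frequency.
#'
#' @param model An `ar_model` from [burg_fit()].
#' @param freqs Frequencies in Hz, `|f| <= sample_rate / 2`.
#' @return Numeric vector of PSD values, same length as `freqs`.
#' @export
ar_psd <- function(model, freqs) {
  stopifnot(inherits(model, "ar_model"))
  freqs <- as.numeric(freqs)
  fs <- model$sample_rate
  if (any(abs(freqs) > fs / 2 + 1e-12)) {
    stop("frequency above the Nyquist limit ", fs / 2, " Hz", call. = FALSE)
  }
  k <- seq_len(model$order)
  # denominator A(e^{j 2 pi f / fs}) for every frequency at once
  ph <- outer(freqs, k, function(f, k) -2i * pi * f * k / fs)
  denom <- 1 + as.vector(exp(ph) %*% model$a)
  model$var / Mod(denom)^2
}

#' Time-frequency spectrum image of a 5-minute HRV segment
#'
#' Slides a window across the uniform tachogram; each window position is
#' mean-removed, fitted with a Burg AR model, and its parametric spectrum
#' evaluated on a uniform grid over the 0-0.4 Hz band of interest. Stacking
#' the spectra (rows ordered by time, columns by frequency) yields the
#' time-frequency spectrum image (TFSI) that the entropy indices summarise.
#'
#' @param segment An [hrv_segment()].
#' @param window_s Sliding-window length in seconds. 64 s at 4 Hz gives 256
#'   samples, comfortably above the `2 p` minimum for an AR(16) fit, while
#'   keeping useful resolution in the VLF band.
#' @param hop_s Hop between window starts in seconds; 4 s yields 60 rows for
#'   a 300 s segment.
#' @param n_freq Number of uniform frequency-grid points on `[0, f_max]`.
#' @param order AR order (16 by default).
#' @param f_max Upper edge of the analysed band in Hz.
#' @return An object of class `tfsi`: `power` (`n_time x n_freq` matrix),
#'   `time_axis` (window-centre times, s), `freq_axis` (Hz), `window_s`,
#'   `hop_s`, `ar_order`, plus the segment's `label` and `record_id`.
#' @export
build_tfsi <- function(segment, window_s = 64, hop_s = 4, n_freq = 256,
                       order = 16, f_max = 0.4) {
  stopifnot(inherits(segment, "hrv_segment"))
  fs <- segment$fs
  if (window_s > segment$duration_s) {
    stop("window_s must not exceed the segment duration", call. = FALSE)
  }
  if (hop_s <= 0) {
    stop("hop_s must be positive", call. = FALSE)
  }
  w_n <- as.integer(round(window_s * fs))
  hop_n <- as.integer(round(hop_s * fs))
  if (w_n <= 2 * order) {
    stop("window too short for AR order ", order, call. = FALSE)
  }
  n <- length(segment$tachogram)
  starts <- seq(1L, n - w_n + 1L, by = hop_n)
  freqs <- seq(0, f_max, length.out = n_freq)
  power <- matrix(NA_real_, nrow = length(starts), ncol = n_freq)
  for (i in seq_along(starts)) {
    chunk <- segment$tachogram[starts[i]:(starts[i] + w_n - 1L)]
    model <- tryCatch(
      burg_fit(chunk, order, sample_rate = fs),
      error = function(e) {
        stop(sprintf("AR fit failed in window %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
    power[i, ] <- ar_psd(model, freqs)
  }
  structure(
    list(
      power = power,
      time_axis = segment$start_s + (starts - 1L) / fs + window_s / 2,
      freq_axis = freqs,
      window_s = window_s, hop_s = hop_s, ar_order = order,
      label = segment$label, record_id = segment$record_id,
      start_s = segment$start_s
    ),
    class = "tfsi"
  )
}

#' @export
print.tfsi <- function(x, ...) {
  cat(sprintf(
    "<tfsi %s @ %gs [%s]: %d x %d (time x frequency), 0-%g Hz>\n",
    x$record_id, x$start_s, x$label, nrow(x$power), ncol(x$power), max(x$freq_axis)
  ))
  invisible(x)
}

#' Export a TFSI as CSV plus a JSON axis sidecar
#'
#' @param tfsi A `tfsi`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tfsi_csv <- function(tfsi, path) {
  stopifnot(inherits(tfsi, "tfsi"))
  utils::write.table(tfsi$power, path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  meta <- list(
    record_id = tfsi$record_id, label = tfsi$label, start_s = tfsi$start_s,
    time_axis = tfsi$time_axis, freq_axis = tfsi$freq_axis,
    window_s = tfsi$window_s, hop_s = tfsi$hop_s, ar_order = tfsi$ar_order
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a TFSI heat map to PNG (time on x, frequency on y)
#'
#' Quick-look export for visual inspection; not a publication graphic.
#'
#' @param tfsi A `tfsi`.
#' @param path Output PNG path.
#' @param log_power Plot `log10` power (usually far more readable).
#' @return `path`, invisibly.
#' @export
write_tfsi_png <- function(tfsi, path, log_power = TRUE) {
  stopifnot(inherits(tfsi, "tfsi"))
  z <- tfsi$power
  if (log_power) z <- log10(z + .Machine$double.eps)
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::image(
    x = tfsi$time_axis, y = tfsi$freq_axis, z = z,
    xlab = "time (s)", ylab = "frequency (Hz)",
    main = sprintf("%s @ %gs [%s]", tfsi$record_id, tfsi$start_s, tfsi$label),
    col = grDevices::hcl.colors(64, "viridis")
  )
  graphics::abline(h = c(0.04, 0.15), col = "white", lwd = 2)
  invisible(path)
}
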