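#' Canonical HRV frequency bands
#'
#' The total analysed band (TP) is 0-0.4 Hz, split into very low frequency
#' (VLF, 0-0.04 Hz), low frequency (LF, 0.04-0.15 Hz) and high frequency
#' (HF, 0.15-0.4 Hz). Membership is half-open, `f_low <= f < f_high`, with
#' the 0.4 Hz upper edge assigned to HF, so every frequency column of a TFSI
#' belongs to exactly one band.
#'
#' @return A data frame with columns `name`, `f_low`, `f_high`.
#' @export
hrv_bands <- function() {
  data.frame(
    name = c("VLF", "LF", "HF"),
    f_low = c(0, 0.04, 0.15),
    f_high = c(0.04, 0.15, 0.4)
  )
}

#' Split a TFSI into VLF/LF/HF sub-images
#'
#' Each frequency column is assigned to exactly one band by half-open
#' membership (0.4 Hz goes to HF); all time rows are retained in every
#' sub-image, so band powers keep their temporal texture.
#'
#' @param tfsi A `tfsi` from [build_tfsi()] whose frequency axis spans
#'   0-0.4 Hz.
#' @return A named list `VLF`, `LF`, `HF` of matrices (time x frequency),
#'   each with a `freq_axis` attribute holding its column frequencies.
#' @export
split_bands <- function(tfsi) {
  stopifnot(inherits(tfsi, "tfsi"))
  f <- tfsi$freq_axis
  if (min(f) > 1e-9 || max(f) < 0.4 - 1e-9) {
    stop("TFSI frequency axis must cover 0-0.4 Hz", call. = FALSE)
  }
  bands <- hrv_bands()
  out <- list()
  for (i in seq_len(nrow(bands))) {
    in_band <- f >= bands$f_low[i] & f < bands$f_high[i]
    if (bands$name[i] == "HF") in_band <- in_band | f >= bands$f_high[i]
    sub <- tfsi$power[, in_band, drop = FALSE]
    attr(sub, "freq_axis") <- f[in_band]
    out[[bands$name[i]]] <- sub
  }
  out
}

#' Pixel-intensity quantizer for image entropy
#'
#' The Shannon entropy of a spectrum image is taken over quantized pixel
#' intensities: `n_levels` equal-width bins spanning the intensity range of
#' the *total* image, shared by all sub-images so that their entropies are
#' comparable and the ratio indices meaningful.
#'
#' @param n_levels Number of quantization levels K (>= 2); 256 by default.
#' @param log_base Base of the entropy logarithm; 10 by default, putting the
#'   attainable maximum at `log10(K)`.
#' @return An object of class `quantizer`.
#' @export
quantizer <- function(n_levels = 256, log_base = 10) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) {
    stop("n_levels must be >= 2", call. = FALSE)
  }
  if (log_base <= 1) {
    stop("log_base must be > 1", call. = FALSE)
  }
  structure(list(n_levels = n_levels, log_base = log_base), class = "quantizer")
}

#' 2-D Shannon entropy of a power (sub-)image
#'
#' Every pixel is mapped to one of K equal-width bins spanning
#' `global_range` (values at the range maximum fall in the top bin);
#' `p_k` is the fraction of this image's pixels in bin k, and
#' `ShEn = -sum_k p_k log(p_k)` over occupied bins. A constant image has
#' entropy 0; pixels spread equally over all K bins give `log(K)` in the
#' quantizer's base.
#'
#' @param image Numeric matrix (or vector) of power values.
#' @param quant A [quantizer()].
#' @param global_range Length-2 numeric `(min, max)` of the parent total
#'   image; defaults to the range of `image` itself.
#' @return The entropy value (units set by `log_base`).
#' @export
shannon_entropy_image <- function(image, quant = quantizer(),
                                  global_range = range(image)) {
  stopifnot(inherits(quant, "quantizer"))
  v <- as.numeric(image)
  if (length(v) == 0) {
    stop("empty image", call. = FALSE)
  }
  if (any(!is.finite(v))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  lo <- global_range[1]
  hi <- global_range[2]
  if (hi < lo) {
    stop("invalid global_range", call. = FALSE)
  }
  k <- quant$n_levels
  if (hi == lo) {
    bins <- rep(1L, length(v))
  } else {
    bins <- pmin(k, 1L + as.integer(floor((v - lo) / (hi - lo) * k)))
    bins <- pmax(bins, 1L) # pixels below the global minimum clamp to bin 1
  }
  p <- tabulate(bins, nbins = k) / length(v)
  p <- p[p > 0]
  -sum(p * log(p, base = quant$log_base))
}

#' The eight MTFSE indices of a TFSI
#'
#' Quantizes with a range taken once from the total image and reused for all
#' band sub-images, then computes the 2-D Shannon entropy of the total image
#' (`ShEnTotal`) and of the VLF/LF/HF sub-images (`ShEnVLF`, `ShEnLF`,
#' `ShEnHF`), plus the ratio indices `ShEnpVLF = ShEnVLF / ShEnTotal` (and
#' analogously pLF, pHF) and `ShEnLFHF = ShEnLF / ShEnHF`. If a ratio's
#' denominator is zero the ratio is reported as `NA` (missing), never a
#' silent division.
#'
#' @param tfsi A `tfsi`.
#' @param quant A [quantizer()].
#' @return A named numeric vector of length 8, in the fixed order
#'   `ShEnVLF, ShEnLF, ShEnHF, ShEnTotal, ShEnpVLF, ShEnpLF, ShEnpHF, ShEnLFHF`.
#' @export
compute_indices <- function(tfsi, quant = quantizer()) {
  stopifnot(inherits(tfsi, "tfsi"))
  rng <- range(tfsi$power)
  sub <- split_bands(tfsi)
  total <- shannon_entropy_image(tfsi$power, quant, rng)
  vlf <- shannon_entropy_image(sub$VLF, quant, rng)
  lf <- shannon_entropy_image(sub$LF, quant, rng)
  hf <- shannon_entropy_image(sub$HF, quant, rng)
  p_vlf <- if (total > 0) vlf / total else NA_real_
  p_lf <- if (total > 0) lf / total else NA_real_
  p_hf <- if (total > 0) hf / total else NA_real_
  lf_hf <- if (hf > 0) lf / hf else NA_real_
  c(
    ShEnVLF = vlf, ShEnLF = lf, ShEnHF = hf, ShEnTotal = total,
    ShEnpVLF = p_vlf, ShEnpLF = p_lf, ShEnpHF = p_hf, ShEnLFHF = lf_hf
  )
}

#' Names of the eight indices, in canonical order
#' @return Character vector of length 8.
#' @export
index_names <- function() {
  c(
    "ShEnVLF", "ShEnLF", "ShEnHF", "ShEnTotal",
    "ShEnpVLF", "ShEnpLF", "ShEnpHF", "ShEnLFHF"
  )
}

#' Feature matrix for a collection of segments
#'
#' Runs [build_tfsi()] and [compute_indices()] on each segment and stacks
#' the results into the feature table used for statistics and
#' classification: one row per segment with provenance, group label and the
#' eight indices.
#'
#' @param segments List of [hrv_segment()] objects.
#' @param config A [mtfse_config()] supplying TFSI and quantizer settings.
#' @return A data frame with columns `record_id`, `start_s`, `label`, then
#'   the eight indices of [index_names()]; ratio indices undefined for a
#'   segment are `NA`.
#' @export
cohort_features <- function(segments, config = mtfse_config()) {
  quant <- quantizer(config$quantizer_levels, config$entropy_log_base)
  rows <- lapply(segments, function(seg) {
    tf <- build_tfsi(seg,
      window_s = config$tfsi_window_s, hop_s = config$tfsi_hop_s,
      n_freq = config$n_freq, order = config$ar_order
    )
    idx <- compute_indices(tf, quant)
    cbind(
      data.frame(
        record_id = seg$record_id, start_s = seg$start_s, label = seg$label,
        stringsAsFactors = FALSE
      ),
      as.data.frame(as.list(idx))
    )
  })
  do.call(rbind, rows)
}

#' Write a feature matrix to CSV (missing values as empty fields)
#'
#' @param features Data frame from [cohort_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature matrix CSV written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return Data frame with provenance columns and the eight indices.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("label", index_names()), names(df))
  if (length(missing_cols)) {
    stop("feature CSV lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
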