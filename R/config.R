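#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default, validates each
#' against the preconditions of the stage that consumes it, and is echoed
#' into every output artifact so results are auditable.
#'
#' @param median_window Median-filter window in beats (odd, >= 3).
#' @param median_rel_threshold Relative artifact threshold in (0, 1).
#' @param resample_hz Tachogram resampling rate in Hz.
#' @param ar_order AR model order.
#' @param tfsi_window_s,tfsi_hop_s Sliding-window length and hop (s) of the
#'   time-frequency image.
#' @param n_freq Frequency-grid points over 0-0.4 Hz.
#' @param quantizer_levels Entropy quantization levels K.
#' @param entropy_log_base Base of the entropy logarithm.
#' @param cv_n_per_group,cv_n_repeats,cv_k Cross-validation protocol:
#'   segments subsampled per group, repetitions, folds.
#' @param classifiers Classifier adapters to run.
#' @param seed Default seed for evaluation and simulation.
#' @return A validated list of class `mtfse_config`.
#' @export
mtfse_config <- function(median_window = 5,
                         median_rel_threshold = 0.2,
                         resample_hz = 4,
                         ar_order = 16,
                         tfsi_window_s = 64,
                         tfsi_hop_s = 4,
                         n_freq = 256,
                         quantizer_levels = 256,
                         entropy_log_base = 10,
                         cv_n_per_group = 300,
                         cv_n_repeats = 500,
                         cv_k = 10,
                         classifiers = c("knn", "svm", "dt"),
                         seed = 1) {
  if (median_window < 3 || median_window %% 2 == 0) {
    stop("median_window must be odd and >= 3", call. = FALSE)
  }
  if (median_rel_threshold <= 0 || median_rel_threshold >= 1) {
    stop("median_rel_threshold must be in (0, 1)", call. = FALSE)
  }
  if (resample_hz <= 0.8) {
    stop("resample_hz must exceed twice the 0.4 Hz band edge", call. = FALSE)
  }
  if (ar_order < 1) stop("ar_order must be >= 1", call. = FALSE)
  if (tfsi_window_s <= 0 || tfsi_window_s > 300) {
    stop("tfsi_window_s must be in (0, 300]", call. = FALSE)
  }
  if (tfsi_hop_s <= 0) stop("tfsi_hop_s must be positive", call. = FALSE)
  if (round(tfsi_window_s * resample_hz) <= 2 * ar_order) {
    stop("tfsi_window_s too short for the AR order at this resample rate", call. = FALSE)
  }
  if (n_freq < 8) stop("n_freq must be >= 8", call. = FALSE)
  if (quantizer_levels < 2) stop("quantizer_levels must be >= 2", call. = FALSE)
  if (entropy_log_base <= 1) stop("entropy_log_base must be > 1", call. = FALSE)
  if (cv_n_per_group < 1 || cv_n_repeats < 1 || cv_k < 2) {
    stop("invalid cross-validation parameters", call. = FALSE)
  }
  bad <- setdiff(classifiers, c("knn", "svm", "dt"))
  if (length(bad)) stop("unknown classifiers: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(
      median_window = as.integer(median_window),
      median_rel_threshold = median_rel_threshold,
      resample_hz = resample_hz,
      ar_order = as.integer(ar_order),
      tfsi_window_s = tfsi_window_s,
      tfsi_hop_s = tfsi_hop_s,
      n_freq = as.integer(n_freq),
      quantizer_levels = as.integer(quantizer_levels),
      entropy_log_base = entropy_log_base,
      cv_n_per_group = as.integer(cv_n_per_group),
      cv_n_repeats = as.integer(cv_n_repeats),
      cv_k = as.integer(cv_k),
      classifiers = classifiers,
      seed = as.integer(seed)
    ),
    class = "mtfse_config"
  )
}

#' Load a pipeline configuration from JSON, merging over the defaults
#'
#' Precedence is defaults < file < `overrides`.
#'
#' @param path Optional JSON file with a subset of [mtfse_config()] fields.
#' @param overrides Named list applied last (e.g. parsed CLI flags).
#' @return A validated `mtfse_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    args <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  known <- names(formals(mtfse_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(mtfse_config, args)
}
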