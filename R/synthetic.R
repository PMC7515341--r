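#' Configuration for the synthetic RR-interval generator
#'
#' Describes a continuous "target tachogram"
#' `r(t) = mean_rr + sum_i amp_i sin(2 pi f_i t + phase_i)` (ms), optionally
#' amplitude-modulated by a slow apnea-like cycle, from which beats are
#' emitted by an integrate-to-threshold rule (the next beat falls one
#' current RR interval after the previous one), with white per-beat jitter
#' and occasional ectopic-like doubled intervals.
#'
#' @param mean_rr Mean RR interval in ms (> 0).
#' @param osc Data frame (or list coercible to one) with columns `freq`
#'   (Hz, < 2), `amp` (ms) and optionally `phase` (rad, default 0): the
#'   deterministic oscillatory components placed in the VLF/LF/HF bands.
#' @param apnea_cycle `NULL`, or `c(period_s, depth)` with period in 25-60 s
#'   and depth in `[0, 1]`: a cosine amplitude modulation of the tachogram
#'   whose troughs mimic the cyclic bradycardia of repetitive apneas.
#'   Minutes containing a modulation trough are annotated `"apnea"`.
#' @param noise_sd SD of white per-beat jitter in ms.
#' @param artifact_rate Per-beat probability of an ectopic-like artifact
#'   (the interval is doubled, as after a missed beat).
#' @param duration_s Record duration in seconds (>= 300 for segment use).
#' @param seed Integer seed; the generator is fully determined by it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(mean_rr = 800,
                         osc = data.frame(freq = numeric(), amp = numeric()),
                         apnea_cycle = NULL,
                         noise_sd = 10,
                         artifact_rate = 0,
                         duration_s = 300,
                         seed = 1) {
  osc <- as.data.frame(osc)
  if (nrow(osc) > 0) {
    if (!all(c("freq", "amp") %in% names(osc))) {
      stop("osc needs columns freq and amp", call. = FALSE)
    }
    if (is.null(osc$phase)) osc$phase <- 0
    if (any(osc$freq <= 0 | osc$freq >= 2)) {
      stop("oscillator frequencies must lie in (0, 2) Hz", call. = FALSE)
    }
  } else {
    osc <- data.frame(freq = numeric(), amp = numeric(), phase = numeric())
  }
  if (mean_rr <= 0) stop("mean_rr must be positive", call. = FALSE)
  if (!is.null(apnea_cycle)) {
    if (length(apnea_cycle) != 2 || apnea_cycle[1] < 25 || apnea_cycle[1] > 60 ||
      apnea_cycle[2] < 0 || apnea_cycle[2] > 1) {
      stop("apnea_cycle must be c(period_s in [25, 60], depth in [0, 1])", call. = FALSE)
    }
  }
  if (noise_sd < 0 || artifact_rate < 0 || artifact_rate > 1) {
    stop("noise_sd must be >= 0 and artifact_rate in [0, 1]", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  structure(
    list(
      mean_rr = mean_rr, osc = osc, apnea_cycle = apnea_cycle,
      noise_sd = noise_sd, artifact_rate = artifact_rate,
      duration_s = duration_s, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Deterministic part of the target tachogram, in ms, at continuous time t.
synth_tachogram <- function(config, t) {
  r <- rep(config$mean_rr, length(t))
  if (nrow(config$osc) > 0) {
    for (i in seq_len(nrow(config$osc))) {
      r <- r + config$osc$amp[i] * sin(2 * pi * config$osc$freq[i] * t + config$osc$phase[i])
    }
  }
  if (!is.null(config$apnea_cycle)) {
    period <- config$apnea_cycle[1]
    depth <- config$apnea_cycle[2]
    r <- r * (1 - depth * (1 + cos(2 * pi * t / period)) / 2)
  }
  r
}

#' Generate a synthetic RR series (and per-minute annotations)
#'
#' Beats are emitted by an integrate-to-threshold rule: the beat after time
#' `t` falls at `t + r(t) / 1000` seconds, where `r(t)` is the modulated
#' target tachogram plus white jitter. Artifacts double a randomly chosen
#' interval with probability `artifact_rate` per beat. When an apnea cycle
#' is configured, every minute containing a modulation trough (times
#' `k * period_s`) is annotated `"apnea"`; otherwise all minutes are
#' `"normal"`. The output is fully determined by `config$seed`.
#'
#' @param config A [synth_config()].
#' @param record_id Label for the emitted record.
#' @return A list with elements `series` (an [rr_series()]) and
#'   `annotations` (a [minute_annotations()]).
#' @export
generate_rr <- function(config, record_id = sprintf("synth-%d", config$seed)) {
  stopifnot(inherits(config, "synth_config"))
  # reject configs whose noiseless tachogram can reach zero before emitting
  amp_sum <- if (nrow(config$osc)) sum(abs(config$osc$amp)) else 0
  depth <- if (is.null(config$apnea_cycle)) 0 else config$apnea_cycle[2]
  if ((config$mean_rr - amp_sum) * (1 - depth) <= 0) {
    stop("config can produce non-positive RR intervals", call. = FALSE)
  }
  with_seed(config$seed, {
    max_beats <- ceiling(config$duration_s * 1000 / (config$mean_rr - amp_sum) * 2) + 10
    beat_times <- numeric(max_beats)
    rr <- numeric(max_beats - 1)
    t <- 0
    i <- 1
    beat_times[1] <- 0
    while (t <= config$duration_s && i < max_beats) {
      rr_i <- synth_tachogram(config, t) +
        if (config$noise_sd > 0) stats::rnorm(1, 0, config$noise_sd) else 0
      if (rr_i <= 0) {
        stop("generated a non-positive RR interval; reduce noise_sd", call. = FALSE)
      }
      t <- t + rr_i / 1000
      rr[i] <- rr_i
      beat_times[i + 1] <- t
      i <- i + 1
    }
    rr <- rr[seq_len(i - 1)]
    if (config$artifact_rate > 0) {
      hit <- stats::runif(length(rr)) < config$artifact_rate
      rr[hit] <- 2 * rr[hit]
    }
    beat_times <- c(0, cumsum(rr) / 1000)
    n_min <- floor(config$duration_s / 60)
    labels <- rep("normal", max(n_min, 1))
    if (!is.null(config$apnea_cycle)) {
      troughs <- seq(0, config$duration_s, by = config$apnea_cycle[1])
      apnea_min <- unique(floor(troughs / 60)) + 1
      apnea_min <- apnea_min[apnea_min <= length(labels)]
      labels[apnea_min] <- "apnea"
    }
    list(
      series = rr_series(beat_times, rr, record_id = record_id),
      annotations = minute_annotations(labels)
    )
  })
}

#' Preset generator configurations
#'
#' Templates for the synthetic study groups:
#' * `"apnea-like"` - sympathetic-dominant profile: strong LF (0.095 Hz),
#'   suppressed HF (0.24 Hz), a 45 s apnea cycle of depth 0.3 (in the VLF
#'   band), mildly elevated artifact rate.
#' * `"normal-like"` - vagal-dominant sleep profile: strong HF, weak LF,
#'   no apnea cycle.
#' * `"lf-dominant"` / `"hf-dominant"` - artifact-free series with a strong
#'   component in one band and a weak one in the other, for separability and
#'   spectral-peak checks (the weak component keeps both band sub-images
#'   textured, so every ratio index stays defined).
#'
#' @param name One of `"apnea-like"`, `"normal-like"`, `"lf-dominant"`,
#'   `"hf-dominant"`.
#' @param seed Seed stored in the returned config.
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("apnea-like", "normal-like", "lf-dominant", "hf-dominant"),
                         seed = 1) {
  name <- match.arg(name)
  switch(name,
    "apnea-like" = synth_config(
      mean_rr = 800,
      osc = data.frame(freq = c(0.095, 0.24), amp = c(50, 15)),
      apnea_cycle = c(45, 0.3),
      noise_sd = 20, artifact_rate = 0.005, duration_s = 300, seed = seed
    ),
    "normal-like" = synth_config(
      mean_rr = 850,
      osc = data.frame(freq = c(0.095, 0.24), amp = c(20, 45)),
      apnea_cycle = NULL,
      noise_sd = 20, artifact_rate = 0.002, duration_s = 300, seed = seed
    ),
    "lf-dominant" = synth_config(
      mean_rr = 800, osc = data.frame(freq = c(0.1, 0.25), amp = c(50, 12)),
      noise_sd = 10, artifact_rate = 0, duration_s = 300, seed = seed
    ),
    "hf-dominant" = synth_config(
      mean_rr = 800, osc = data.frame(freq = c(0.25, 0.1), amp = c(50, 12)),
      noise_sd = 10, artifact_rate = 0, duration_s = 300, seed = seed
    )
  )
}

#' Generate a labeled cohort of preprocessed synthetic segments
#'
#' For each group, draws `n_per_group` records from the group's template
#' with per-record seeds derived deterministically from `seed`
#' (`seed + 10000 * group_index + record_index`), runs each through the
#' preprocessing pipeline (median filter, then cubic-spline resampling of
#' the first 5 minutes) and labels the segment with the group name.
#'
#' @param n_per_group Segments per group (>= 1).
#' @param groups Named list of [synth_config()] templates; defaults to the
#'   `apnea-like` and `normal-like` presets.
#' @param seed Master seed for per-record seed derivation.
#' @param config Pipeline settings ([mtfse_config()]) for the median filter
#'   and resampling.
#' @return A list of [hrv_segment()] objects, `n_per_group` per group, with
#'   `label` set to the group name.
#' @export
generate_cohort <- function(n_per_group,
                            groups = list(
                              "apnea-like" = synth_preset("apnea-like"),
                              "normal-like" = synth_preset("normal-like")
                            ),
                            seed = 1,
                            config = mtfse_config()) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list of synth_config templates", call. = FALSE)
  }
  segments <- list()
  for (g in seq_along(groups)) {
    template <- groups[[g]]
    stopifnot(inherits(template, "synth_config"))
    for (i in seq_len(n_per_group)) {
      member_id <- sprintf("%s-%03d", names(groups)[g], i)
      template$seed <- as.integer(seed + 10000 * g + i)
      seg <- tryCatch(
        {
          rec <- generate_rr(template, record_id = member_id)
          clean <- remove_artifacts(rec$series,
            window = config$median_window,
            rel_threshold = config$median_rel_threshold
          )
          win <- structure(
            list(
              beat_times = clean$beat_times, rr_ms = clean$rr_ms,
              start_s = 0, label = names(groups)[g], record_id = member_id
            ),
            class = "rr_window"
          )
          interpolate_resample(win, fs = config$resample_hz)
        },
        error = function(e) {
          stop(sprintf(
            "cohort member %s failed preprocessing: %s",
            member_id, conditionMessage(e)
          ), call. = FALSE)
        }
      )
      segments[[length(segments) + 1]] <- seg
    }
  }
  segments
}
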