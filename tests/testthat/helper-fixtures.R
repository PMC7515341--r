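# Shared fixtures, built in code and cached for the session.

# A clean rr_series with a prescribed RR sequence (ms).
rr_from_intervals <- function(rr_ms, t0 = 0, record_id = "fixture") {
  rr_series(t0 + c(0, cumsum(rr_ms) / 1000), rr_ms, record_id = record_id)
}

# A raw 5-min window sampling RR(t) = mean + amp * sin(2 pi f t + phase)
# at its own beat times (beat emitted one current interval after the last).
sine_window <- function(mean_rr = 800, amp = 50, freq = 0.1, phase = 0,
                        duration = 300, label = "sine") {
  t <- 0
  beats <- 0
  while (t <= duration + 2) {
    t <- t + (mean_rr + amp * sin(2 * pi * freq * t + phase)) / 1000
    beats <- c(beats, t)
  }
  # knot values are the closed form evaluated at the beat that ends the interval
  rr <- mean_rr + amp * sin(2 * pi * freq * beats[-1] + phase)
  structure(
    list(beat_times = beats, rr_ms = rr, start_s = 0, label = label, record_id = "sine"),
    class = "rr_window"
  )
}

# Cache one small labeled feature matrix for evaluation tests.
.fixture_env <- new.env(parent = emptyenv())

small_cohort_features <- function() {
  if (is.null(.fixture_env$features)) {
    segs <- generate_cohort(25, seed = 42)
    .fixture_env$features <- cohort_features(segs)
  }
  .fixture_env$features
}

# Burg oracle: at each lattice stage, find the reflection coefficient by
# numerical minimisation of the summed forward+backward squared prediction
# error (the defining least-squares problem), independent of the analytic
# update used by burg_fit().
burg_numeric_oracle <- function(x, p) {
  x <- x - mean(x)
  n <- length(x)
  f <- x
  b <- x
  a <- numeric(0)
  for (m in seq_len(p)) {
    ff <- f[(m + 1):n]
    bb <- b[m:(n - 1)]
    obj <- function(k) sum((ff + k * bb)^2) + sum((bb + k * ff)^2)
    k <- stats::optimize(obj, c(-1, 1), tol = 1e-12)$minimum
    a <- c(a + k * rev(a), k)
    fn <- ff + k * bb
    bn <- bb + k * ff
    f[(m + 1):n] <- fn
    b[(m + 1):n] <- bn
  }
  a
}

# Entropy oracle: naive two-pass histogram + sum over -p log p.
entropy_naive_oracle <- function(values, n_levels, log_base, lo, hi) {
  counts <- numeric(n_levels)
  for (v in as.numeric(values)) {
    if (hi == lo) {
      bin <- 1
    } else {
      bin <- floor((v - lo) / (hi - lo) * n_levels) + 1
      if (bin > n_levels) bin <- n_levels
      if (bin < 1) bin <- 1
    }
    counts[bin] <- counts[bin] + 1
  }
  total <- sum(counts)
  h <- 0
  for (c_k in counts) {
    if (c_k > 0) {
      p <- c_k / total
      h <- h - p * log(p, base = log_base)
    }
  }
  h
}
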