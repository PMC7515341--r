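test_that("rr_series validates its invariants", {
  expect_error(rr_series(c(0, 1, 1)), "strictly increasing")
  expect_error(rr_series(c(0, 1, 2), c(1000, -5)), "positive")
  expect_error(rr_series(c(0, 1, 2), c(1000, 1000, 1000)), "length")
  rr <- rr_series(c(0, 0.8, 1.6))
  expect_equal(rr$rr_ms, c(800, 800))
})

test_that("median filter leaves clean series unchanged and fixes spikes", {
  clean <- rr_from_intervals(c(800, 810, 805, 795, 800))
  expect_equal(remove_artifacts(clean)$rr_ms, clean$rr_ms)

  const <- rr_from_intervals(rep(750, 20))
  expect_equal(remove_artifacts(const)$rr_ms, const$rr_ms)

  # spike replaced by the 5-point window median (brute-force: median of
  # sorted {795, 800, 805, 810, 2000} = 805)
  spiky <- rr_from_intervals(c(800, 810, 2000, 805, 795))
  fixed <- remove_artifacts(spiky, window = 5, rel_threshold = 0.2)
  expect_equal(fixed$rr_ms, c(800, 810, 805, 805, 795))
  expect_length(fixed$rr_ms, length(spiky$rr_ms))
  # beat times rebuilt by cumulative summation from the first beat
  expect_equal(fixed$beat_times, c(0, cumsum(fixed$rr_ms) / 1000))
})

test_that("median filter is idempotent and length-preserving on random series", {
  set.seed(301)
  for (i in 1:10) {
    rr_ms <- 800 + rnorm(120, 0, 30)
    spikes <- sample(10:110, 4)
    rr_ms[spikes] <- rr_ms[spikes] * 2
    rr <- rr_from_intervals(rr_ms)
    once <- remove_artifacts(rr)
    twice <- remove_artifacts(once)
    expect_length(once$rr_ms, length(rr_ms))
    expect_equal(twice$rr_ms, once$rr_ms)
  }
})

test_that("median filter rejects bad arguments and short series", {
  rr <- rr_from_intervals(rep(800, 3))
  expect_error(remove_artifacts(rr, window = 5), "insufficient data")
  rr10 <- rr_from_intervals(rep(800, 10))
  expect_error(remove_artifacts(rr10, window = 4), "odd")
  expect_error(remove_artifacts(rr10, rel_threshold = 1.2), "rel_threshold")
})

test_that("segment_and_label applies the A/C labeling and discard rules", {
  rr <- rr_from_intervals(rep(800, 800)) # 640 s ~ 10.6 min
  ann_a <- rep("normal", 10)
  ann_a[4] <- "apnea" # minute index 3 (zero-based)
  wins <- segment_and_label(rr, ann_a, record_class = "A")
  expect_length(wins, 2)
  expect_equal(vapply(wins, `[[`, "", "label"), c("A-OSA", "A-N"))
  expect_equal(vapply(wins, `[[`, 0, "start_s"), c(0, 300))

  ann_c <- rep("normal", 10)
  ann_c[8] <- "apnea"
  wins_c <- segment_and_label(rr, ann_c, record_class = "C")
  expect_length(wins_c, 1)
  expect_equal(wins_c[[1]]$label, "C-N")
  expect_equal(wins_c[[1]]$start_s, 0)

  # a 4-minute record yields no complete window
  short <- rr_from_intervals(rep(800, 280))
  expect_length(segment_and_label(short, rep("normal", 4), "A"), 0)

  expect_error(segment_and_label(rr, character(0), "A"), "empty")
})

test_that("class-A tiling conserves windows: A-OSA + A-N = complete windows", {
  set.seed(302)
  for (i in 1:5) {
    n_min <- sample(10:25, 1)
    rr <- rr_from_intervals(rep(750, ceiling(n_min * 60 / 0.75) + 10))
    ann <- sample(c("apnea", "normal"), n_min, replace = TRUE)
    wins <- segment_and_label(rr, ann, "A")
    expect_length(wins, n_min %/% 5)
  }
})

test_that("spline resampling hits the 4 Hz grid and reproduces smooth signals", {
  win <- sine_window(mean_rr = 800, amp = 0, freq = 0.1)
  seg <- interpolate_resample(win)
  expect_length(seg$tachogram, 1200)
  expect_equal(seg$tachogram, rep(800, 1200))

  # analytic sinusoid recovered at interior grid points
  win2 <- sine_window(mean_rr = 800, amp = 50, freq = 0.1)
  seg2 <- interpolate_resample(win2)
  grid <- seq(0, by = 0.25, length.out = 1200)
  interior <- grid > 5 & grid < 295
  expected <- 800 + 50 * sin(2 * pi * 0.1 * grid)
  expect_lt(max(abs(seg2$tachogram[interior] - expected[interior])), 1)
})

test_that("spline resampling is deterministic and validates input", {
  win <- sine_window(amp = 30, freq = 0.2)
  expect_identical(interpolate_resample(win)$tachogram, interpolate_resample(win)$tachogram)

  too_few <- structure(
    list(
      beat_times = c(0, 100, 200), rr_ms = c(800, 805),
      start_s = 0, label = "x", record_id = "x"
    ),
    class = "rr_window"
  )
  expect_error(interpolate_resample(too_few), "fewer than 4 beats")
})

test_that("RR CSV round-trips through read/write", {
  rr <- rr_from_intervals(c(800, 810, 790, 805, 800), record_id = "abc")
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rr, path)
  back <- read_rr_csv(path, record_id = "abc")
  expect_equal(back$beat_times, rr$beat_times)
  expect_equal(back$rr_ms, rr$rr_ms)
})
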