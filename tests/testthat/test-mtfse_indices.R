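# A TFSI stub with prescribed power and a 256-point 0-0.4 Hz axis.
tfsi_stub <- function(power, n_freq = ncol(power)) {
  structure(
    list(
      power = power,
      time_axis = seq_len(nrow(power)),
      freq_axis = seq(0, 0.4, length.out = n_freq),
      window_s = 64, hop_s = 4, ar_order = 16,
      label = "stub", record_id = "stub", start_s = 0
    ),
    class = "tfsi"
  )
}

random_tfsi <- function(n_time = 12, n_freq = 64) {
  tfsi_stub(matrix(rexp(n_time * n_freq), n_time, n_freq), n_freq)
}

test_that("band split partitions the frequency columns with half-open edges", {
  tf <- random_tfsi(6, 256)
  sub <- split_bands(tf)
  f <- tf$freq_axis
  # brute-force enumeration of the 256 grid frequencies
  expect_equal(ncol(sub$VLF), sum(f < 0.04))
  expect_equal(ncol(sub$LF), sum(f >= 0.04 & f < 0.15))
  expect_equal(ncol(sub$HF), sum(f >= 0.15))
  expect_equal(ncol(sub$VLF) + ncol(sub$LF) + ncol(sub$HF), 256)
  expect_equal(nrow(sub$VLF), nrow(tf$power))
  # 0.4 Hz lands in HF
  expect_true(0.4 %in% attr(sub$HF, "freq_axis"))
  # pairwise disjoint
  expect_length(
    intersect(attr(sub$VLF, "freq_axis"), attr(sub$LF, "freq_axis")), 0
  )
})

test_that("power confined to 0.2 Hz leaves VLF and LF sub-images zero", {
  f <- seq(0, 0.4, length.out = 256)
  power <- matrix(0, 5, 256)
  power[, which.min(abs(f - 0.2))] <- 7
  sub <- split_bands(tfsi_stub(power))
  expect_true(all(sub$VLF == 0))
  expect_true(all(sub$LF == 0))
  expect_gt(max(sub$HF), 0)
})

test_that("split_bands rejects an axis that does not cover 0-0.4 Hz", {
  tf <- random_tfsi(4, 64)
  tf$freq_axis <- seq(0, 0.2, length.out = 64)
  expect_error(split_bands(tf), "0-0.4")
})

test_that("image entropy has the closed-form values on canonical cases", {
  q2 <- quantizer(4, log_base = 2)
  # constant image: single occupied bin
  expect_equal(shannon_entropy_image(matrix(3, 5, 5), q2, c(3, 3)), 0)
  # pixels spread equally over all K bins: log_base(K)
  v <- matrix(c(0.1, 0.35, 0.6, 0.85), 2, 2)
  expect_equal(shannon_entropy_image(v, q2, c(0, 1)), 2) # log2(4)
  # p = {0.5, 0.25, 0.25} in base 2 -> 1.5 bits
  v2 <- matrix(c(0.1, 0.1, 0.4, 0.9), 2, 2)
  expect_equal(shannon_entropy_image(v2, quantizer(4, 2), c(0, 1)), 1.5)
})

test_that("image entropy agrees with the naive histogram oracle", {
  set.seed(401)
  for (i in 1:20) {
    img <- matrix(rexp(300, rate = runif(1, 0.5, 2)), 15, 20)
    rng <- range(img)
    for (k in c(8, 256)) {
      for (base in c(2, 10)) {
        got <- shannon_entropy_image(img, quantizer(k, base), rng)
        want <- entropy_naive_oracle(img, k, base, rng[1], rng[2])
        expect_equal(got, want, tolerance = 1e-12)
        expect_gte(got, 0)
        expect_lte(got, log(k, base = base) + 1e-12)
      }
    }
  }
})

test_that("the eight indices obey their definitional identities", {
  set.seed(402)
  for (i in 1:25) {
    tf <- random_tfsi()
    idx <- compute_indices(tf)
    expect_named(idx, index_names())
    expect_identical(unname(idx["ShEnpVLF"]), unname(idx["ShEnVLF"] / idx["ShEnTotal"]))
    expect_identical(unname(idx["ShEnpLF"]), unname(idx["ShEnLF"] / idx["ShEnTotal"]))
    expect_identical(unname(idx["ShEnpHF"]), unname(idx["ShEnHF"] / idx["ShEnTotal"]))
    expect_identical(unname(idx["ShEnLFHF"]), unname(idx["ShEnLF"] / idx["ShEnHF"]))
    expect_true(all(idx[1:4] >= 0 & idx[1:4] <= log10(256) + 1e-12))
  }
})

test_that("indices are invariant under positive rescaling of the TFSI", {
  set.seed(403)
  for (scale in c(10, 0.001, 7.3)) {
    tf <- random_tfsi()
    tf_scaled <- tf
    tf_scaled$power <- tf$power * scale
    expect_equal(compute_indices(tf), compute_indices(tf_scaled), tolerance = 1e-12)
  }
})

test_that("zero-denominator ratios are reported missing, not divided", {
  tf <- tfsi_stub(matrix(5, 4, 256)) # constant image: all entropies 0
  idx <- compute_indices(tf)
  expect_equal(unname(idx[c("ShEnVLF", "ShEnLF", "ShEnHF", "ShEnTotal")]), rep(0, 4))
  expect_true(all(is.na(idx[c("ShEnpVLF", "ShEnpLF", "ShEnpHF", "ShEnLFHF")])))
})

test_that("LF-dominant segments score higher ShEnLF/HF than HF-dominant ones", {
  diffs <- numeric(20)
  for (i in 1:20) {
    lf_cfg <- synth_preset("lf-dominant", seed = 500 + i)
    hf_cfg <- synth_preset("hf-dominant", seed = 500 + i)
    seg_lf <- generate_cohort(1, groups = list(lf = lf_cfg), seed = 600 + i)[[1]]
    seg_hf <- generate_cohort(1, groups = list(hf = hf_cfg), seed = 700 + i)[[1]]
    i_lf <- compute_indices(build_tfsi(seg_lf))
    i_hf <- compute_indices(build_tfsi(seg_hf))
    diffs[i] <- i_lf["ShEnLFHF"] - i_hf["ShEnLFHF"]
  }
  expect_true(all(diffs > 0))
})

test_that("feature extraction produces the fixed column layout and CSV round-trip", {
  segs <- generate_cohort(2, seed = 9)
  fx <- cohort_features(segs)
  expect_equal(names(fx), c("record_id", "start_s", "label", index_names()))
  expect_equal(nrow(fx), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fx, path)
  back <- read_features_csv(path)
  expect_equal(back[index_names()], fx[index_names()], tolerance = 1e-12)
})
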