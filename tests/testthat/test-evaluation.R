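test_that("confusion metrics reproduce the closed-form definitions", {
  expect_equal(
    compute_metrics(tp = 50, fp = 0, tn = 50, fn = 0),
    c(Acc = 100, Sen = 100, Spe = 100)
  )
  expect_equal(
    compute_metrics(tp = 9, fp = 2, tn = 8, fn = 1),
    c(Acc = 85, Sen = 90, Spe = 80)
  )
  m <- compute_metrics(tp = 0, fp = 0, tn = 10, fn = 0)
  expect_true(is.na(m["Sen"]))
  expect_equal(unname(m[c("Acc", "Spe")]), c(100, 100))
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
})

test_that("metrics agree with a brute-force recount of fold predictions", {
  set.seed(501)
  truth <- sample(c("pos", "neg"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, sample(c("pos", "neg"), 200, replace = TRUE))
  tp <- sum(truth == "pos" & pred == "pos")
  fp <- sum(truth == "neg" & pred == "pos")
  tn <- sum(truth == "neg" & pred == "neg")
  fn <- sum(truth == "pos" & pred == "neg")
  m <- compute_metrics(tp, fp, tn, fn)
  expect_equal(unname(m["Acc"]), mean(truth == pred) * 100)
  expect_equal(unname(m["Sen"]), mean(pred[truth == "pos"] == "pos") * 100)
  expect_equal(unname(m["Spe"]), mean(pred[truth == "neg"] == "neg") * 100)
})

test_that("Welch t-tests behave on identical, separated and degenerate groups", {
  fx <- data.frame(label = rep(c("g1", "g2"), each = 4))
  for (nm in index_names()) fx[[nm]] <- rep(c(1, 2, 3, 4), 2)
  tt <- index_ttests(fx)
  expect_true(all(tt$p_value == 1)) # identical samples: zero mean difference
  expect_true(all(tt$stars == ""))

  set.seed(502)
  fx2 <- data.frame(label = rep(c("g1", "g2"), each = 50))
  for (nm in index_names()) fx2[[nm]] <- c(rnorm(50, 0, 1), rnorm(50, 5, 1))
  tt2 <- index_ttests(fx2)
  expect_true(all(tt2$p_value < 0.001))
  expect_true(all(tt2$stars == "***"))

  # zero variance in both groups: p undefined, not an error
  fx3 <- data.frame(label = rep(c("g1", "g2"), each = 3))
  for (nm in index_names()) fx3[[nm]] <- 1
  expect_true(all(is.na(index_ttests(fx3)$p_value)))

  # n = 1 in one group violates the precondition
  fx4 <- fx2[c(1, 51:60), ]
  expect_error(index_ttests(fx4), ">= 2 samples")
})

test_that("repeated CV is perfect on separated groups and seed-deterministic", {
  set.seed(503)
  fx <- data.frame(label = rep(c("a", "b"), each = 40))
  for (nm in index_names()) {
    fx[[nm]] <- c(runif(40, 0, 1), runif(40, 10, 11))
  }
  for (clf in c("knn", "svm", "dt")) {
    ev <- repeated_cv(fx, clf, n_per_group = 40, n_repeats = 3, k = 10, seed = 1)
    expect_equal(ev$summary$Acc, 100)
  }
  e1 <- repeated_cv(fx, "knn", n_per_group = 40, n_repeats = 3, k = 10, seed = 2)
  e2 <- repeated_cv(fx, "knn", n_per_group = 40, n_repeats = 3, k = 10, seed = 2)
  expect_identical(e1$per_rep, e2$per_rep)
  expect_error(repeated_cv(fx, "boost"), "should be one of")
})

test_that("subsampling shrinks to the smallest group with a warning", {
  fx <- small_cohort_features()
  expect_warning(
    ev <- repeated_cv(fx, "knn", n_per_group = 300, n_repeats = 2, k = 5, seed = 4),
    "reduced"
  )
  expect_equal(ev$n_per_group, min(table(fx$label)))
})

test_that("per-repetition confusion counts cover every test instance", {
  fx <- small_cohort_features()
  ev <- repeated_cv(fx, "dt", n_per_group = 20, n_repeats = 4, k = 5, seed = 6)
  expect_equal(sum(ev$rate_table >= 0), 4)
  expect_equal(unname(rowSums(ev$rate_table)), c(100, 100), tolerance = 1e-9)
})

test_that("three-group evaluation reports per-class one-vs-rest rows plus a macro mean", {
  set.seed(504)
  fx <- data.frame(label = rep(c("g1", "g2", "g3"), each = 30))
  for (nm in index_names()) {
    fx[[nm]] <- c(rnorm(30, 0), rnorm(30, 6), rnorm(30, 12))
  }
  ev <- repeated_cv(fx, "knn", n_per_group = 30, n_repeats = 2, k = 5, seed = 7)
  expect_equal(ev$summary$class, c("g1", "g2", "g3", "mean"))
  expect_equal(dim(ev$rate_table), c(3, 3))
  expect_equal(unname(rowSums(ev$rate_table)), rep(100, 3), tolerance = 1e-9)
  mean_row <- ev$summary[ev$summary$class == "mean", ]
  class_rows <- ev$summary[ev$summary$class != "mean", ]
  expect_equal(mean_row$Acc, mean(class_rows$Acc))
  expect_true(all(ev$summary$Acc >= 0 & ev$summary$Acc <= 100))
})

test_that("rows with missing indices are excluded and counted", {
  fx <- small_cohort_features()
  fx$ShEnLFHF[c(1, 30)] <- NA
  tt <- index_ttests(fx)
  expect_equal(attr(tt, "excluded"), 2)
  ev <- repeated_cv(fx, "knn", n_per_group = 10, n_repeats = 2, k = 5, seed = 8)
  expect_equal(ev$excluded_missing, 2)
})
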