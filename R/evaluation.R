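#' Welch t-tests of every index between every group pair
#'
#' Screens the eight indices for group differences: for each index and each
#' pair of groups, a two-sided Welch (unequal-variance) two-sample t-test,
#' alongside the per-group mean and SD. Significance stars follow the usual
#' 0.05 / 0.01 / 0.001 convention.
#'
#' @param features Feature data frame ([cohort_features()] layout): a
#'   `label` column plus the eight index columns. Rows with a missing index
#'   value are excluded (and counted in the `excluded` attribute).
#' @return A data frame with one row per (index, group pair):
#'   `index, group1, group2, mean1, sd1, mean2, sd2, p_value, stars`.
#'   `p_value` is `NA` when both groups are degenerate (zero variance).
#' @export
index_ttests <- function(features) {
  idx <- intersect(index_names(), names(features))
  if (!length(idx) || is.null(features$label)) {
    stop("features must contain a label column and index columns", call. = FALSE)
  }
  complete <- stats::complete.cases(features[idx])
  excluded <- sum(!complete)
  features <- features[complete, , drop = FALSE]
  groups <- sort(unique(features$label))
  if (length(groups) < 2) {
    stop("need at least two groups for t-tests", call. = FALSE)
  }
  if (any(table(features$label) < 2)) {
    stop("every group needs >= 2 samples for a t-test", call. = FALSE)
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (name in idx) {
    for (pr in pairs) {
      x <- features[features$label == pr[1], name]
      y <- features[features$label == pr[2], name]
      p <- tryCatch(
        stats::t.test(x, y, var.equal = FALSE)$p.value,
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1]] <- data.frame(
        index = name, group1 = pr[1], group2 = pr[2],
        mean1 = mean(x), sd1 = stats::sd(x),
        mean2 = mean(y), sd2 = stats::sd(y),
        p_value = p,
        stars = if (is.na(p)) {
          ""
        } else if (p < 0.001) {
          "***"
        } else if (p < 0.01) {
          "**"
        } else if (p < 0.05) {
          "*"
        } else {
          ""
        },
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP + TN) / (TP + FP + TN + FN) * 100`,
#' `Sen = TP / (TP + FN) * 100`, `Spe = TN / (FP + TN) * 100`.
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Named numeric vector `c(Acc, Sen, Spe)` in percent.
#' @examples
#' compute_metrics(tp = 9, fp = 2, tn = 8, fn = 1) # 85, 90, 80
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- tp + fp + tn + fn
  if (total == 0) {
    stop("confusion table is empty", call. = FALSE)
  }
  c(
    Acc = (tp + tn) / total * 100,
    Sen = if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_,
    Spe = if (fp + tn > 0) tn / (fp + tn) * 100 else NA_real_
  )
}

# One classifier adapter call: train on (x_tr, y_tr), predict labels of x_te.
# Each adapter runs at its ecosystem's defaults: class::knn with k = 1,
# e1071::svm (C-classification, radial kernel, cost 1, gamma = 1/ncol,
# scale = TRUE), rpart with its default control and method = "class".
classify_fold <- function(classifier, x_tr, y_tr, x_te) {
  switch(classifier,
    knn = class::knn(train = x_tr, test = x_te, cl = y_tr, k = 1),
    svm = {
      fit <- e1071::svm(x = x_tr, y = y_tr, type = "C-classification")
      stats::predict(fit, x_te)
    },
    dt = {
      df_tr <- data.frame(x_tr, .y = y_tr)
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      stats::predict(fit, data.frame(x_te), type = "class")
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

classifier_defaults <- function(classifier) {
  switch(classifier,
    knn = "class::knn, k = 1",
    svm = "e1071::svm, C-classification, radial kernel, cost = 1, gamma = 1/n_features, scale = TRUE",
    dt = "rpart::rpart, method = class, default rpart.control"
  )
}

# Stratified fold assignment: within each class, shuffle rows and deal them
# round-robin into k folds.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    if (length(idx) < k) {
      stop("fewer than k samples of class ", g, " in a repetition", call. = FALSE)
    }
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated, subsampled, stratified k-fold cross-validation
#'
#' The evaluation protocol for the MTFSE indices: per repetition, draw
#' `n_per_group` segments from each group without replacement, run
#' stratified k-fold cross-validation with the chosen classifier at its
#' ecosystem defaults, pool the fold confusion counts, and compute accuracy,
#' sensitivity and specificity; the report averages over repetitions. For
#' two groups, sensitivity treats `positive` as the positive class. For
#' three or more, per-class one-vs-rest Acc/Sen/Spe are reported with their
#' macro mean, plus the row-normalised classification-rate table (each row
#' sums to 100%).
#'
#' @param features Feature data frame ([cohort_features()] layout). Rows
#'   with missing index values are excluded and counted.
#' @param classifier `"knn"`, `"svm"` or `"dt"`.
#' @param n_per_group Segments drawn per group per repetition; reduced (with
#'   a warning) to the smallest group size when a group is smaller.
#' @param n_repeats Number of subsample-and-fold repetitions.
#' @param k Number of folds.
#' @param seed Seed for subsampling and fold assignment.
#' @param positive Positive class for two-group sensitivity; defaults to a
#'   group matching "OSA"/"apnea", else the first group alphabetically.
#' @return An object of class `mtfse_eval`: per-repetition metrics
#'   (`per_rep`), their means (`summary`), the mean confusion-rate table
#'   (`rate_table`), and the run metadata (classifier, defaults string,
#'   `n_per_group`, `k`, `n_repeats`, `seed`, excluded-row count).
#' @export
repeated_cv <- function(features, classifier = c("knn", "svm", "dt"),
                        n_per_group = 300, n_repeats = 500, k = 10,
                        seed = 1, positive = NULL) {
  classifier <- match.arg(classifier)
  idx_cols <- intersect(index_names(), names(features))
  if (!length(idx_cols) || is.null(features$label)) {
    stop("features must contain a label column and index columns", call. = FALSE)
  }
  complete <- stats::complete.cases(features[idx_cols])
  excluded <- sum(!complete)
  features <- features[complete, , drop = FALSE]
  groups <- sort(unique(features$label))
  if (length(groups) < 2) {
    stop("need at least two groups to classify", call. = FALSE)
  }
  sizes <- table(features$label)
  n_sub <- n_per_group
  if (min(sizes) < n_per_group) {
    n_sub <- min(sizes)
    warning(sprintf(
      "smallest group has %d segments; subsample size reduced from %d to %d",
      min(sizes), n_per_group, n_sub
    ), call. = FALSE)
  }
  if (is.null(positive)) {
    hit <- grep("OSA|apnea", groups, ignore.case = TRUE, value = TRUE)
    positive <- if (length(hit)) hit[1] else groups[1]
  }
  binary <- length(groups) == 2
  x_all <- as.matrix(features[idx_cols])
  y_all <- factor(features$label, levels = groups)

  per_rep <- vector("list", n_repeats)
  conf_sum <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      take <- unlist(lapply(groups, function(g) sample(which(y_all == g), n_sub)))
      x <- x_all[take, , drop = FALSE]
      y <- droplevels(y_all[take])
      folds <- stratified_folds(as.character(y), k)
      conf <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
      for (f in seq_len(k)) {
        te <- folds == f
        pred <- classify_fold(classifier, x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
        conf <- conf + table(
          factor(as.character(y[te]), levels = groups),
          factor(as.character(pred), levels = groups)
        )
      }
      conf_sum <- conf_sum + conf
      per_rep[[rep_i]] <- cv_metrics_from_confusion(conf, groups, positive, binary)
    }
  })
  per_rep <- do.call(rbind, per_rep)
  summary_tab <- stats::aggregate(per_rep[c("Acc", "Sen", "Spe")],
    by = list(class = per_rep$class), FUN = mean, na.rm = TRUE
  )
  rate_table <- sweep(conf_sum, 1, rowSums(conf_sum), "/") * 100
  structure(
    list(
      classifier = classifier,
      classifier_defaults = classifier_defaults(classifier),
      groups = groups, positive = if (binary) positive else NA_character_,
      n_per_group = n_sub, k = k, n_repeats = n_repeats, seed = seed,
      excluded_missing = excluded,
      per_rep = per_rep, summary = summary_tab, rate_table = rate_table
    ),
    class = "mtfse_eval"
  )
}

# Metrics for one repetition's pooled k x k confusion table (rows = truth).
cv_metrics_from_confusion <- function(conf, groups, positive, binary) {
  if (binary) {
    neg <- setdiff(groups, positive)
    tp <- conf[positive, positive]
    fn <- conf[positive, neg]
    fp <- conf[neg, positive]
    tn <- conf[neg, neg]
    m <- compute_metrics(tp, fp, tn, fn)
    data.frame(class = "overall", Acc = m["Acc"], Sen = m["Sen"], Spe = m["Spe"], row.names = NULL)
  } else {
    rows <- lapply(groups, function(g) {
      tp <- conf[g, g]
      fn <- sum(conf[g, ]) - tp
      fp <- sum(conf[, g]) - tp
      tn <- sum(conf) - tp - fn - fp
      m <- compute_metrics(tp, fp, tn, fn)
      data.frame(class = g, Acc = m["Acc"], Sen = m["Sen"], Spe = m["Spe"], row.names = NULL)
    })
    out <- do.call(rbind, rows)
    rbind(out, data.frame(
      class = "mean", Acc = mean(out$Acc), Sen = mean(out$Sen), Spe = mean(out$Spe)
    ))
  }
}

#' @export
print.mtfse_eval <- function(x, ...) {
  cat(sprintf(
    "<mtfse_eval %s: %s; %d reps x %d-fold, %d/group, seed %d>\n",
    x$classifier, paste(x$groups, collapse = " vs "),
    x$n_repeats, x$k, x$n_per_group, x$seed
  ))
  print(x$summary, digits = 4)
  invisible(x)
}
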