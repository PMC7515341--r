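#' Simulate a cohort of synthetic records to disk
#'
#' Writes one RR CSV (`time_s,rr_ms`) plus one JSON annotation sidecar
#' (`<id>.ann.json`, holding `record_class` and `minute_labels`) per
#' synthetic record, using per-record seeds derived from `seed`. Group
#' templates default to the apnea-like (class "A") and normal-like
#' (class "C") presets.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_group Records per group.
#' @param groups Named list of [synth_config()] templates.
#' @param record_classes Named character vector mapping group name to the
#'   record class "A" or "C" used at extraction time.
#' @param seed Master seed.
#' @param config Pipeline configuration echoed into the run manifest.
#' @return Invisibly, the manifest data frame (record id, group, paths).
#' @export
cmd_simulate <- function(out_dir, n_per_group = 10,
                         groups = list(
                           "apnea-like" = synth_preset("apnea-like"),
                           "normal-like" = synth_preset("normal-like")
                         ),
                         record_classes = c("apnea-like" = "A", "normal-like" = "C"),
                         seed = 1, config = mtfse_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (g in seq_along(groups)) {
    template <- groups[[g]]
    gname <- names(groups)[g]
    for (i in seq_len(n_per_group)) {
      template$seed <- as.integer(seed + 10000 * g + i)
      id <- sprintf("%s-%03d", gname, i)
      rec <- generate_rr(template, record_id = id)
      csv_path <- file.path(out_dir, paste0(id, ".csv"))
      ann_path <- file.path(out_dir, paste0(id, ".ann.json"))
      write_rr_csv(rec$series, csv_path)
      jsonlite::write_json(
        list(
          record_id = id, group = gname,
          record_class = unname(record_classes[gname] %||% "C"),
          minute_labels = as.character(rec$annotations),
          seed = template$seed
        ),
        ann_path,
        auto_unbox = TRUE, digits = NA
      )
      rows[[length(rows) + 1]] <- data.frame(
        record_id = id, group = gname, csv = csv_path, annotations = ann_path,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(
    list(config = unclass(config), seed = seed, records = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

# Read one record (RR CSV + optional .ann.json sidecar) into labeled segments.
extract_record <- function(csv_path, config) {
  rr <- read_rr_csv(csv_path)
  clean <- remove_artifacts(rr,
    window = config$median_window,
    rel_threshold = config$median_rel_threshold
  )
  ann_path <- sub("\\.csv$", ".ann.json", csv_path)
  if (file.exists(ann_path)) {
    meta <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
    ann <- minute_annotations(meta$minute_labels)
    record_class <- meta$record_class %||% "C"
  } else {
    n_min <- floor(max(clean$beat_times) / 60)
    if (n_min < 5) stop("record shorter than 5 minutes and no annotations", call. = FALSE)
    ann <- minute_annotations(rep("normal", n_min))
    record_class <- "C"
  }
  windows <- segment_and_label(clean, ann, record_class = record_class)
  lapply(windows, interpolate_resample, fs = config$resample_hz)
}

#' Extract MTFSE features from RR CSV records
#'
#' Runs the full per-segment pipeline (median filter, segmentation and
#' labeling, spline resampling, TFSI, entropy indices) over a batch of RR
#' CSV files. Per-record failures are logged and skipped; the call errors
#' only if no record yields a segment.
#'
#' @param inputs Character vector of RR CSV paths, or a directory containing
#'   them.
#' @param config A [mtfse_config()].
#' @param out Optional path for the feature CSV.
#' @return The feature data frame ([cohort_features()] layout), with the
#'   effective config in attribute `config` and per-record failures in
#'   attribute `failures`.
#' @export
cmd_extract <- function(inputs, config = mtfse_config(), out = NULL) {
  if (length(inputs) == 1 && dir.exists(inputs)) {
    inputs <- list.files(inputs, pattern = "\\.csv$", full.names = TRUE)
    inputs <- inputs[!grepl("features", basename(inputs))]
  }
  if (!length(inputs)) {
    stop("no input records found", call. = FALSE)
  }
  failures <- character(0)
  segments <- list()
  for (path in inputs) {
    segs <- tryCatch(extract_record(path, config), error = function(e) {
      message(sprintf("[mtfse] skipping %s: %s", basename(path), conditionMessage(e)))
      failures <<- c(failures, sprintf("%s: %s", basename(path), conditionMessage(e)))
      NULL
    })
    segments <- c(segments, segs)
  }
  if (!length(segments)) {
    stop("no segments could be extracted from the inputs", call. = FALSE)
  }
  features <- cohort_features(segments, config)
  attr(features, "config") <- unclass(config)
  attr(features, "failures") <- failures
  if (!is.null(out)) {
    write_features_csv(features, out)
    jsonlite::write_json(
      list(config = unclass(config), n_segments = nrow(features), failures = failures),
      paste0(out, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  features
}

#' Evaluate a feature matrix: t-tests and repeated cross-validation
#'
#' Runs [index_ttests()] over all group pairs, then [repeated_cv()] for
#' every configured classifier on every pairwise task and (with three or
#' more groups) the all-groups task.
#'
#' @param features Feature data frame or path to a feature CSV.
#' @param config A [mtfse_config()] (classifiers, CV protocol, seed).
#' @param out_dir Optional directory for report files (JSON report plus
#'   t-test and summary CSV tables).
#' @return A list of class `mtfse_report`: `ttests`, `cv` (nested list
#'   task -> classifier -> `mtfse_eval`), `config`, `excluded_missing`.
#' @export
cmd_evaluate <- function(features, config = mtfse_config(), out_dir = NULL) {
  if (is.character(features)) {
    features <- read_features_csv(features)
  }
  groups <- sort(unique(features$label))
  if (length(groups) < 2) {
    stop("evaluation needs at least two groups", call. = FALSE)
  }
  ttests <- index_ttests(features)
  tasks <- utils::combn(groups, 2, simplify = FALSE)
  if (length(groups) >= 3) tasks <- c(tasks, list(groups))
  cv <- list()
  for (task in tasks) {
    task_name <- paste(task, collapse = "&")
    cv[[task_name]] <- list()
    for (clf in config$classifiers) {
      cv[[task_name]][[clf]] <- repeated_cv(
        features[features$label %in% task, , drop = FALSE],
        classifier = clf,
        n_per_group = config$cv_n_per_group,
        n_repeats = config$cv_n_repeats,
        k = config$cv_k,
        seed = config$seed
      )
    }
  }
  report <- structure(
    list(
      ttests = ttests, cv = cv, config = unclass(config),
      excluded_missing = attr(ttests, "excluded")
    ),
    class = "mtfse_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ttests, file.path(out_dir, "ttests.csv"), row.names = FALSE)
    summaries <- list()
    for (task_name in names(cv)) {
      for (clf in names(cv[[task_name]])) {
        ev <- cv[[task_name]][[clf]]
        s <- ev$summary
        s$task <- task_name
        s$classifier <- clf
        summaries[[length(summaries) + 1]] <- s
      }
    }
    utils::write.csv(do.call(rbind, summaries),
      file.path(out_dir, "cv_summary.csv"),
      row.names = FALSE
    )
    json_cv <- lapply(cv, function(by_clf) {
      lapply(by_clf, function(ev) {
        list(
          classifier = ev$classifier, classifier_defaults = ev$classifier_defaults,
          groups = ev$groups, positive = ev$positive,
          n_per_group = ev$n_per_group, k = ev$k,
          n_repeats = ev$n_repeats, seed = ev$seed,
          excluded_missing = ev$excluded_missing,
          summary = ev$summary, rate_table = as.data.frame(ev$rate_table)
        )
      })
    })
    jsonlite::write_json(
      list(config = unclass(config), ttests = ttests, cv = json_cv),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' @export
print.mtfse_report <- function(x, ...) {
  cat("<mtfse_report>\n t-tests:", nrow(x$ttests), "comparisons\n tasks:\n")
  for (task_name in names(x$cv)) {
    for (clf in names(x$cv[[task_name]])) {
      s <- x$cv[[task_name]][[clf]]$summary
      overall <- s[s$class %in% c("overall", "mean"), ]
      cat(sprintf(
        "  %-28s %-4s Acc %6.2f%%  Sen %6.2f%%  Spe %6.2f%%\n",
        task_name, clf, overall$Acc, overall$Sen, overall$Spe
      ))
    }
  }
  invisible(x)
}
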