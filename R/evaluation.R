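## Leave-one-subject-out evaluation over protocol scenarios and
## within/between-age-group designs.
##
## Scenarios fix which protocol(s) feed training and which are tested:
##   S1A semi-structured -> semi-structured     S1B semi-structured -> real-life
##   S2A combined        -> combined            S2B combined        -> real-life
##   S3A real-life       -> real-life
## Age designs fix the training/testing cohorts:
##   within_old old->old, within_young young->young,
##   y_trained_btw young->old, yando_trained_btw {young,old}->old.
## Folds always iterate over the TEST cohort's subjects; the held-out
## subject is removed from training entirely (all cohorts, all protocols),
## while training-only cohorts (e.g. the young cohort in y_trained_btw) are
## never folded and contribute all their subjects to every fold.

#' Scenario registry
#'
#' Machine-readable protocol scenarios. Variant A tests on the training
#' protocol composition; variant B tests on real-life data only.
#'
#' @param id One of `"S1A"`, `"S1B"`, `"S2A"`, `"S2B"`, `"S3A"`.
#' @return List with `id`, `train_protocols`, `test_protocols`.
#' @export
scenario_spec <- function(id) {
  reg <- list(
    S1A = list(train = "semi_structured",  test = "semi_structured"),
    S1B = list(train = "semi_structured",  test = "real_life"),
    S2A = list(train = PATD_PROTOCOLS,     test = PATD_PROTOCOLS),
    S2B = list(train = PATD_PROTOCOLS,     test = "real_life"),
    S3A = list(train = "real_life",        test = "real_life"))
  if (!id %in% names(reg)) {
    stop(sprintf("unknown scenario '%s' (known: %s)", id,
                 paste(names(reg), collapse = ", ")))
  }
  list(id = id, train_protocols = reg[[id]]$train, test_protocols = reg[[id]]$test)
}

#' Age-design registry
#'
#' @param id One of `"within_old"`, `"within_young"`, `"y_trained_btw"`,
#'   `"yando_trained_btw"`.
#' @return List with `id`, `train_cohorts`, `test_cohort`.
#' @export
age_model_spec <- function(id) {
  reg <- list(
    within_old       = list(train = "old",              test = "old"),
    within_young     = list(train = "young",            test = "young"),
    y_trained_btw    = list(train = "young",            test = "old"),
    yando_trained_btw = list(train = c("young", "old"), test = "old"))
  if (!id %in% names(reg)) {
    stop(sprintf("unknown age design '%s' (known: %s)", id,
                 paste(names(reg), collapse = ", ")))
  }
  list(id = id, train_cohorts = reg[[id]]$train, test_cohort = reg[[id]]$test)
}

#' Leave-one-subject-out folds
#'
#' @param subject_ids Character vector of at least two subject ids.
#' @return List of `n` folds, each `list(train_ids, test_id)`; every subject
#'   is the test subject of exactly one fold.
#' @export
l1so_folds <- function(subject_ids) {
  subject_ids <- unique(subject_ids)
  if (length(subject_ids) < 2L) stop("L1SO requires at least 2 subjects")
  lapply(subject_ids, function(s) {
    list(train_ids = setdiff(subject_ids, s), test_id = s)
  })
}

empty_confusion <- function() {
  matrix(0L, nrow = 6L, ncol = 6L,
         dimnames = list(truth = PATD_ACTIVITIES, prediction = PATD_ACTIVITIES))
}

confusion_matrix <- function(truth, prediction) {
  cm <- empty_confusion()
  tab <- table(factor(truth, levels = PATD_ACTIVITIES),
               factor(prediction, levels = PATD_ACTIVITIES))
  cm[] <- as.integer(tab)
  cm
}

#' F1 score from a precision/recall pair
#'
#' Harmonic mean of precision and recall, on the percentage scale; 0 when
#' both are 0.
#'
#' @param precision,recall Percentages.
#' @return F1 in percent.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Rows of the matrix are ground truth, columns predictions. Metrics are in
#' percent; a zero denominator yields 0 by convention.
#'
#' @param confusion K x K confusion matrix (counts).
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  tp <- diag(confusion)
  col_tot <- colSums(confusion)
  row_tot <- rowSums(confusion)
  precision <- ifelse(col_tot > 0, 100 * tp / col_tot, 0)
  recall <- ifelse(row_tot > 0, 100 * tp / row_tot, 0)
  f1 <- f1_score(precision, recall)
  data.frame(class = rownames(confusion), precision = precision,
             recall = recall, f1 = f1, row.names = NULL)
}

#' Overall accuracy (%) of a confusion matrix
#'
#' @param confusion Confusion matrix with at least one count.
#' @return `100 * trace / total`.
#' @export
overall_accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(confusion)) / total
}

#' Mutual confusion rate between two classes (%)
#'
#' The share of true `class_a` and `class_b` windows misclassified as the
#' other class: `100 * (n_ab + n_ba) / (row_a + row_b)`. Used to compare the
#' running/walking confusion structure across cohorts. Returns 0 when both
#' rows are empty.
#'
#' @param confusion Confusion matrix with named rows/columns.
#' @param class_a,class_b Two distinct class names.
#' @return Percentage in \[0, 100\].
#' @export
confusion_pair_rate <- function(confusion, class_a, class_b) {
  stopifnot(class_a != class_b,
            all(c(class_a, class_b) %in% rownames(confusion)))
  denom <- sum(confusion[class_a, ]) + sum(confusion[class_b, ])
  if (denom == 0) return(0)
  100 * (confusion[class_a, class_b] + confusion[class_b, class_a]) / denom
}

#' Run one evaluation design
#'
#' Executes one (scenario, age design) cell: leave-one-subject-out folds over
#' the test cohort's subjects; per fold the model is trained on the training
#' cohorts' windows restricted to the scenario's training protocols with the
#' held-out subject removed entirely, then tested on the held-out subject's
#' windows restricted to the test protocols. Metrics are pooled (micro)
#' across folds and reported per held-out subject.
#'
#' @param x Either a list of [subject_record()]s (features are then built via
#'   [build_feature_table()]) or a prebuilt feature table covering the
#'   cohorts/protocols the design requires.
#' @param scenario A [scenario_spec()] or its id string.
#' @param age_spec An [age_model_spec()] or its id string.
#' @param config A [model_config()].
#' @param seg_config A [segmentation_config()] (used only when `x` is a list
#'   of records).
#' @return A `patd_report`: pooled and per-fold confusion matrices, per-class
#'   precision/recall/F1 (%), overall accuracy (%), per-held-out-subject
#'   accuracies, fold train/test subject ids and dropped-window accounting.
#' @export
run_design <- function(x, scenario, age_spec, config,
                       seg_config = segmentation_config()) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.character(age_spec)) age_spec <- age_model_spec(age_spec)
  table <- if (data.table::is.data.table(x) || is.data.frame(x)) {
    data.table::as.data.table(x)
  } else {
    build_feature_table(x, config, seg_config)
  }

  test_subjects <- sort(unique(table$subject_id[table$cohort == age_spec$test_cohort]))
  if (length(test_subjects) < 2L) {
    stop(sprintf("design '%s' needs >= 2 subjects in test cohort '%s'",
                 age_spec$id, age_spec$test_cohort))
  }
  folds <- l1so_folds(test_subjects)

  pooled <- empty_confusion()
  fold_out <- list()
  subj_acc <- numeric(0)
  skipped <- character(0)
  model <- NULL
  model_key <- NULL
  for (f in folds) {
    train_rows <- table$cohort %in% age_spec$train_cohorts &
      table$protocol %in% scenario$train_protocols &
      table$subject_id != f$test_id
    test_rows <- table$subject_id == f$test_id &
      table$protocol %in% scenario$test_protocols
    if (!any(test_rows)) {
      warning(sprintf("fold '%s': empty test partition, skipped", f$test_id))
      skipped <- c(skipped, f$test_id)
      next
    }
    train_tbl <- table[which(train_rows), ]
    test_tbl <- table[which(test_rows), ]
    data.table::setattr(train_tbl, "feature_names", feature_cols(table))
    data.table::setattr(test_tbl, "feature_names", feature_cols(table))
    ## training is seeded, so identical training sets yield identical
    ## forests; reuse the model when the held-out subject was never in the
    ## training cohorts (e.g. cross-cohort designs train on the same set
    ## for every fold)
    train_key <- paste(sort(unique(train_tbl$subject_id)), collapse = "|")
    if (is.null(model) || !identical(train_key, model_key)) {
      model <- train_patd(train_tbl, config)
      model_key <- train_key
    }
    pred <- predict_patd(model, test_tbl)
    cm <- confusion_matrix(test_tbl$label, pred)
    pooled <- pooled + cm
    subj_acc[f$test_id] <- overall_accuracy(cm)
    fold_out[[f$test_id]] <- list(
      test_id = f$test_id,
      train_subjects = sort(unique(train_tbl$subject_id)),
      confusion = cm, n_test = nrow(test_tbl))
  }
  if (!length(fold_out)) stop("all folds had empty test partitions")

  structure(list(
    scenario = scenario, age_spec = age_spec, config = config,
    folds = fold_out,
    confusion = pooled,
    overall_accuracy = overall_accuracy(pooled),
    per_class = precision_recall_f1(pooled),
    per_subject_accuracy = subj_acc,
    skipped_folds = skipped,
    gps_dropped = attr(table, "gps_dropped") %||% 0L),
    class = "patd_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patd_report <- function(x, ...) {
  cat(sprintf("<patd_report> scenario %s x %s | %s / %s\n",
              x$scenario$id, x$age_spec$id, x$config$sensor_mode, x$config$scope))
  cat(sprintf("  overall accuracy: %.2f%% over %d windows, %d folds\n",
              x$overall_accuracy, sum(x$confusion), length(x$folds)))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-18s P %6.2f  R %6.2f  F1 %6.2f\n",
                pc$class[i], pc$precision[i], pc$recall[i], pc$f1[i]))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (machine-readable metrics), `confusion.csv` (labeled
#' pooled confusion matrix) and `report.txt` (aligned human-readable table)
#' into `dir`.
#'
#' @param report A `patd_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obj <- list(
    scenario = report$scenario$id, age_design = report$age_spec$id,
    sensor_mode = report$config$sensor_mode, scope = report$config$scope,
    overall_accuracy = report$overall_accuracy,
    per_class = report$per_class,
    per_subject_accuracy = as.list(report$per_subject_accuracy),
    gps_dropped = report$gps_dropped,
    skipped_folds = report$skipped_folds)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cm <- data.table::as.data.table(report$confusion, keep.rownames = "truth")
  data.table::fwrite(cm, file.path(dir, "confusion.csv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
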