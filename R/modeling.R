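## Feature tables and random-forest models.
##
## Two model scopes mirror the study design: an "individual" model uses one
## position's 85 features per window; the "general" model fuses all five
## positions by concatenating their feature vectors for windows aligned on
## the same start time (425 features), expressing cross-position patterns.
## Each scope comes in an ACC-only and an ACC+GPS flavour; the latter adds
## gps_avg_speed and gps_elev_diff and drops windows without a valid GPS
## feature pair (no imputation; the drop count is recorded).

META_COLS <- c("subject_id", "cohort", "protocol", "position", "t_start", "label")

#' Model configuration
#'
#' @param sensor_mode `"acc"` (accelerometer only) or `"acc_gps"`.
#' @param scope `"general"` (all five positions fused) or
#'   `"individual:<position>"`, e.g. `"individual:right_knee"`.
#' @param n_trees Number of trees in the random forest (default 500).
#' @param max_features_rule Per-split candidate feature rule; `"sqrt"`
#'   (default) uses floor(sqrt(p)).
#' @param seed Integer seed controlling forest randomness.
#' @return A named list of class `patd_model_config`.
#' @export
model_config <- function(sensor_mode = c("acc", "acc_gps"), scope = "general",
                         n_trees = 500, max_features_rule = "sqrt", seed = 1L) {
  sensor_mode <- match.arg(sensor_mode)
  if (scope != "general") {
    pos <- sub("^individual:", "", scope)
    if (!grepl("^individual:", scope) || !pos %in% PATD_POSITIONS) {
      stop(sprintf("scope must be 'general' or 'individual:<position>', got '%s'", scope))
    }
  }
  structure(list(sensor_mode = sensor_mode, scope = scope,
                 n_trees = as.integer(n_trees),
                 max_features_rule = max_features_rule,
                 seed = as.integer(seed)),
            class = "patd_model_config")
}

scope_positions <- function(scope) {
  if (scope == "general") PATD_POSITIONS else sub("^individual:", "", scope)
}

## Features of every labelable window of one position of one subject.
## Fast path over segment(): operates on index ranges, no window objects.
featurize_position <- function(record, position, config = segmentation_config()) {
  acc <- record$acc[[position]]$data
  idx <- window_index(acc$t, config$window_len_s, config$step_s)
  idx <- idx[idx$n >= config$min_fill_frac * config$window_len_s * config$fs_hz, ]
  if (nrow(idx) == 0L) return(NULL)
  lab <- window_labels(idx$t_start, config$window_len_s, record$labels,
                       config$purity_min)
  keep <- which(!is.na(lab$activity))
  if (!length(keep)) return(NULL)
  idx <- idx[keep, ]; lab <- lab[keep, ]

  t <- acc$t; ax <- acc$ax; ay <- acc$ay; az <- acc$az
  feats <- matrix(NA_real_, nrow = nrow(idx), ncol = 85L,
                  dimnames = list(NULL, acc_feature_names()))
  for (k in seq_len(nrow(idx))) {
    r <- idx$i0[k]:idx$i1[k]
    feats[k, ] <- acc_features(list(t = t[r], ax = ax[r], ay = ay[r], az = az[r]),
                               fs_hz = config$fs_hz)
  }
  cbind(data.table::data.table(
    subject_id = record$subject_id, cohort = record$cohort,
    protocol = lab$protocol, position = position,
    t_start = idx$t_start, label = lab$activity),
    data.table::as.data.table(feats))
}

## GPS feature pair per window start for one subject (position-independent).
gps_feature_rows <- function(record, starts, window_len_s) {
  n <- length(starts)
  out <- data.table::data.table(subject_id = record$subject_id, t_start = starts,
                                gps_avg_speed = NA_real_, gps_elev_diff = NA_real_,
                                gps_valid = FALSE)
  if (is.null(record$gps)) return(out)
  g <- record$gps$data
  for (k in seq_len(n)) {
    f <- g[g$t >= starts[k] & g$t < starts[k] + window_len_s, ]
    gf <- window_gps_features(f)
    if (gf$valid) {
      data.table::set(out, i = k, j = "gps_avg_speed", value = gf$avg_speed)
      data.table::set(out, i = k, j = "gps_elev_diff", value = gf$elev_diff)
      data.table::set(out, i = k, j = "gps_valid", value = TRUE)
    }
  }
  out
}

#' Featurize every labeled window of a dataset once
#'
#' Computes the 85 accelerometer features for every labeled window of every
#' position of every subject, plus the per-window GPS feature pair, in one
#' pass. The result can be fed to [build_feature_table()] repeatedly to
#' assemble tables for different scopes and sensor modes without
#' recomputing features.
#'
#' @param records List of [subject_record()]s.
#' @param seg_config A [segmentation_config()].
#' @return List with `acc` (long data.table: metadata columns plus the 85
#'   features, one row per labeled window per position) and `gps`
#'   (data.table `subject_id, t_start, gps_avg_speed, gps_elev_diff,
#'   gps_valid`, one row per window start per subject).
#' @export
featurize_dataset <- function(records, seg_config = segmentation_config()) {
  acc_parts <- list()
  gps_parts <- list()
  for (rec in records) {
    for (p in names(rec$acc)) {
      ft <- featurize_position(rec, p, seg_config)
      if (!is.null(ft)) acc_parts[[paste(rec$subject_id, p)]] <- ft
    }
    sub_parts <- acc_parts[paste(rec$subject_id, names(rec$acc))]
    starts <- sort(unique(unlist(lapply(sub_parts, function(x) x$t_start))))
    if (length(starts)) {
      gps_parts[[rec$subject_id]] <-
        gps_feature_rows(rec, starts, seg_config$window_len_s)
    }
  }
  if (!length(acc_parts)) stop("no labeled windows in any record")
  list(acc = data.table::rbindlist(acc_parts),
       gps = data.table::rbindlist(gps_parts))
}

#' Assemble a feature table for a model configuration
#'
#' Builds the windows-by-features table the classifier consumes. Individual
#' scope yields one row per labeled window of the named position (85 feature
#' columns); general scope yields one row per window start time at which all
#' five positions produced a labeled window, with the positions' feature
#' vectors concatenated under position-prefixed names (425 columns). In
#' `acc_gps` mode two GPS columns are appended and rows without a valid GPS
#' pair (< 2 fixes in the window) are dropped; the number of dropped rows is
#' recorded in the `gps_dropped` attribute. Subjects missing a position
#' required by the general scope are excluded with a warning.
#'
#' @param records List of [subject_record()]s (may be `NULL` when `features`
#'   is supplied).
#' @param config A [model_config()].
#' @param seg_config A [segmentation_config()].
#' @param features Optional precomputed [featurize_dataset()] result.
#' @return A `data.table` with metadata columns `subject_id`, `cohort`,
#'   `protocol`, `t_start`, `label` (plus `position` for individual scope)
#'   followed by feature columns; attribute `feature_names` holds the
#'   feature column names in contract order.
#' @export
build_feature_table <- function(records, config,
                                seg_config = segmentation_config(),
                                features = NULL) {
  stopifnot(inherits(config, "patd_model_config"))
  if (is.null(features)) features <- featurize_dataset(records, seg_config)
  positions <- scope_positions(config$scope)
  long <- features$acc

  have <- long[, list(npos = length(unique(position))), by = "subject_id"]
  if (length(positions) == 1L) {
    tbl <- long[long$position == positions, ]
    if (nrow(tbl) == 0L) stop(sprintf("no windows at position '%s'", positions))
    tbl <- data.table::copy(tbl)
  } else {
    pos_by_subj <- long[, list(ok = all(positions %in% unique(position))),
                        by = "subject_id"]
    bad <- pos_by_subj$subject_id[!pos_by_subj$ok]
    if (length(bad)) {
      warning(sprintf("subject(s) %s lack position(s) required by scope '%s'; excluded",
                      paste(bad, collapse = ", "), config$scope))
    }
    keep <- long[!long$subject_id %in% bad, ]
    if (nrow(keep) == 0L) stop("no usable subjects for the general scope")
    parts <- lapply(positions, function(p) {
      part <- keep[keep$position == p, ]
      data.table::setnames(part, acc_feature_names(),
                           paste0(p, "_", acc_feature_names()))
      part[, "position" := NULL]
      if (p != positions[1]) part[, c("cohort", "protocol", "label") := NULL]
      part
    })
    tbl <- Reduce(function(a, b) merge(a, b, by = c("subject_id", "t_start")),
                  parts)
    data.table::setcolorder(
      tbl, c("subject_id", "cohort", "protocol", "t_start", "label"))
  }

  gps_dropped <- 0L
  if (config$sensor_mode == "acc_gps") {
    tbl <- merge(tbl, features$gps, by = c("subject_id", "t_start"),
                 all.x = TRUE, sort = FALSE)
    n0 <- nrow(tbl)
    tbl <- tbl[which(tbl$gps_valid), ]
    gps_dropped <- n0 - nrow(tbl)
    tbl[, "gps_valid" := NULL]
  }
  feature_names <- setdiff(names(tbl), META_COLS)
  stopifnot(!anyNA(tbl[, feature_names, with = FALSE]))
  data.table::setattr(tbl, "feature_names", feature_names)
  data.table::setattr(tbl, "gps_dropped", gps_dropped)
  tbl
}

feature_cols <- function(table) {
  fn <- attr(table, "feature_names")
  if (is.null(fn)) fn <- setdiff(names(table), META_COLS)
  fn
}

#' Train a random-forest activity classifier
#'
#' Fits a random forest (via \pkg{ranger}) on the feature columns of a
#' feature table. Metadata columns are never fed to the classifier. Training
#' is deterministic given `config$seed` (single-threaded).
#'
#' @param table A feature table from [build_feature_table()] (or any
#'   data.frame with the same metadata/feature column convention) with at
#'   least two classes present.
#' @param config A [model_config()].
#' @return A `patd_model`: fitted forest plus config, ordered feature-name
#'   list and class list.
#' @export
train_patd <- function(table, config) {
  fn <- feature_cols(table)
  y <- factor(table$label, levels = PATD_ACTIVITIES)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("training table must contain at least 2 classes")
  x <- as.data.frame(table)[, fn, drop = FALSE]
  if (anyNA(x)) stop("feature columns must not contain missing values")
  mtry <- switch(config$max_features_rule,
                 sqrt = max(1L, floor(sqrt(length(fn)))),
                 stop(sprintf("unknown max_features_rule '%s'", config$max_features_rule)))
  fit <- ranger::ranger(x = x, y = y, num.trees = config$n_trees, mtry = mtry,
                        seed = config$seed, num.threads = 1L,
                        verbose = FALSE)
  structure(list(fit = fit, config = config, feature_names = fn,
                 classes = levels(y),
                 package_version = as.character(utils::packageVersion("patd"))),
            class = "patd_model")
}

#' Predict activity labels for a feature table
#'
#' Columns are aligned to the model's stored feature order by name, so column
#' order in `table` is irrelevant; missing or extra feature columns are a
#' hard error naming the offenders.
#'
#' @param model A `patd_model` from [train_patd()].
#' @param table Feature table whose feature-name set matches the model's.
#' @return Character vector of predicted activity labels (empty for an empty
#'   table).
#' @export
predict_patd <- function(model, table) {
  stopifnot(inherits(model, "patd_model"))
  fn <- feature_cols(table)
  missing_f <- setdiff(model$feature_names, fn)
  extra_f <- setdiff(fn, model$feature_names)
  if (length(missing_f) || length(extra_f)) {
    stop(sprintf("feature schema mismatch: missing [%s]; extra [%s]",
                 paste(missing_f, collapse = ", "),
                 paste(extra_f, collapse = ", ")))
  }
  if (nrow(table) == 0L) return(character(0))
  x <- as.data.frame(table)[, model$feature_names, drop = FALSE]
  ## fixed seed: predict.ranger otherwise draws its tie-breaking seed from
  ## the R RNG, making repeated runs state-dependent
  as.character(stats::predict(model$fit, data = x, num.threads = 1L,
                              seed = model$config$seed)$predictions)
}

#' Save / load a trained model
#'
#' Models are persisted with the package version that produced them; loading
#' under a different major.minor package version is refused.
#'
#' @param model A `patd_model`.
#' @param path File path.
#' @return `path` (save) or the restored `patd_model` (load).
#' @export
save_patd_model <- function(model, path) {
  stopifnot(inherits(model, "patd_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_patd_model
#' @export
load_patd_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "patd_model")) stop("not a patd model file")
  mm <- function(v) paste(strsplit(v, ".", fixed = TRUE)[[1]][1:2], collapse = ".")
  here <- as.character(utils::packageVersion("patd"))
  if (mm(model$package_version) != mm(here)) {
    stop(sprintf("model was saved by patd %s; refusing to load under %s",
                 model$package_version, here))
  }
  model
}
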