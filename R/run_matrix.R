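## End-to-end orchestration: simulate -> featurize -> evaluate over the full
## scenario x age-design x sensor-mode x scope grid, with structured
## line-oriented JSON logging and a flat summary table.

PATD_LOG_SCHEMA <- 1L

#' Run configuration
#'
#' @param scenarios Scenario ids (subset of S1A, S1B, S2A, S2B, S3A).
#' @param age_designs Age design ids (subset of within_old, within_young,
#'   y_trained_btw, yando_trained_btw).
#' @param sensor_modes Subset of `c("acc", "acc_gps")`.
#' @param scopes Model scopes; default the general model plus the five
#'   individual models.
#' @param n_trees Trees per forest.
#' @param seed Base seed for model fitting.
#' @param seg_config A [segmentation_config()].
#' @return A named list of class `patd_run_config`.
#' @export
run_config <- function(scenarios = c("S1A", "S1B", "S2A", "S2B", "S3A"),
                       age_designs = c("within_old", "within_young",
                                       "y_trained_btw", "yando_trained_btw"),
                       sensor_modes = c("acc", "acc_gps"),
                       scopes = c("general", paste0("individual:", PATD_POSITIONS)),
                       n_trees = 500, seed = 1L,
                       seg_config = segmentation_config()) {
  for (s in scenarios) scenario_spec(s)
  for (a in age_designs) age_model_spec(a)
  stopifnot(all(sensor_modes %in% c("acc", "acc_gps")))
  for (sc in scopes) model_config(scope = sc)  # validates
  structure(list(scenarios = scenarios, age_designs = age_designs,
                 sensor_modes = sensor_modes, scopes = scopes,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 seg_config = seg_config),
            class = "patd_run_config")
}

log_record <- function(log, event, ...) {
  rec <- c(list(schema = PATD_LOG_SCHEMA, event = event), list(...))
  c(log, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}

#' Run the full evaluation matrix
#'
#' Builds one feature table per (sensor mode, scope) combination and runs
#' every requested (scenario, age design) cell on it. Cells that are
#' infeasible on the given data (e.g. a cohort absent, or a protocol with no
#' windows) are skipped with a log record and the run continues. The whole
#' run is deterministic given the records and `config$seed`.
#'
#' @param records List of [subject_record()]s covering the cohorts the
#'   designs require.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `summary.csv`, `log.jsonl` and one report directory per cell.
#' @return List with `summary` (data.table: one row per completed cell with
#'   overall accuracy and per-class F1), `reports` (named list of
#'   `patd_report`s keyed `scenario.design.mode.scope`) and `log` (character
#'   vector of JSON log lines).
#' @export
run_matrix <- function(records, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "patd_run_config"))
  log <- character(0)
  reports <- list()
  rows <- list()
  features <- featurize_dataset(records, config$seg_config)
  log <- log_record(log, "featurized", n_windows = nrow(features$acc),
                    n_subjects = length(unique(features$acc$subject_id)))

  for (mode in config$sensor_modes) {
    for (scope in config$scopes) {
      mcfg <- model_config(sensor_mode = mode, scope = scope,
                           n_trees = config$n_trees, seed = config$seed)
      table <- tryCatch(
        build_feature_table(records, mcfg, config$seg_config, features = features),
        error = function(e) e)
      if (inherits(table, "error")) {
        log <- log_record(log, "table_failed", mode = mode, scope = scope,
                          message = conditionMessage(table))
        next
      }
      log <- log_record(log, "table_built", mode = mode, scope = scope,
                        n_windows = nrow(table),
                        gps_dropped = attr(table, "gps_dropped"))
      for (sc in config$scenarios) {
        for (ad in config$age_designs) {
          cell_id <- paste(sc, ad, mode, scope, sep = ".")
          rep <- tryCatch(
            run_design(table, sc, ad, mcfg, config$seg_config),
            error = function(e) e)
          if (inherits(rep, "error")) {
            log <- log_record(log, "cell_skipped", cell = cell_id,
                              message = conditionMessage(rep))
            next
          }
          reports[[cell_id]] <- rep
          f1 <- stats::setNames(rep$per_class$f1,
                                paste0("f1_", rep$per_class$class))
          rows[[cell_id]] <- data.table::data.table(
            scenario = sc, age_design = ad, sensor_mode = mode, scope = scope,
            overall_accuracy = rep$overall_accuracy,
            n_windows = sum(rep$confusion), t(f1))
          log <- log_record(log, "cell_done", cell = cell_id,
                            accuracy = rep$overall_accuracy,
                            n_windows = sum(rep$confusion))
        }
      }
    }
  }
  summary <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table()

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    data.table::fwrite(summary, file.path(out_dir, "summary.csv"), eol = "\n")
    writeLines(log, file.path(out_dir, "log.jsonl"))
    for (cell in names(reports)) {
      write_report(reports[[cell]], file.path(out_dir, cell))
    }
  }
  list(summary = summary, reports = reports, log = log)
}
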