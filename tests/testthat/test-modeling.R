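# A linearly separable two-class toy table in the package's column convention
toy_table <- function(n_per_class = 40, n_subjects = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  dt <- data.table::data.table(
    subject_id = rep(sprintf("s%02d", seq_len(n_subjects)), length.out = n),
    cohort = "young", protocol = "semi_structured",
    position = "chest",
    t_start = seq_len(n),
    label = rep(c("walking", "running"), each = n_per_class),
    f_a = c(rnorm(n_per_class, 0), rnorm(n_per_class, 10)),
    f_b = rnorm(n))
  data.table::setattr(dt, "feature_names", c("f_a", "f_b"))
  dt
}

test_that("model_config validates scope and mode", {
  expect_error(model_config("magnetometer"))
  expect_error(model_config("acc", scope = "individual:wrist"))
  expect_error(model_config("acc", scope = "knee"))
  cfg <- model_config("acc_gps", "individual:right_knee", n_trees = 10)
  expect_equal(cfg$n_trees, 10L)
})

test_that("individual tables have 85 feature columns, general 425", {
  fz <- tiny_features()
  recs <- tiny_cohorts()
  ind <- build_feature_table(recs, model_config("acc", "individual:chest"),
                             features = fz)
  expect_identical(attr(ind, "feature_names"), acc_feature_names())
  expect_true(all(ind$position == "chest"))
  gen <- build_feature_table(recs, model_config("acc", "general"),
                             features = fz)
  fn <- attr(gen, "feature_names")
  expect_length(fn, 425)
  expect_true(all(paste0("chest_", acc_feature_names()) %in% fn))
  expect_true(all(paste0("right_knee_", acc_feature_names()) %in% fn))
  # general rows require all five positions at a window start
  expect_lte(nrow(gen), nrow(ind))
})

test_that("acc_gps tables append the GPS pair and drop invalid rows", {
  fz <- tiny_features()
  recs <- tiny_cohorts()
  acc <- build_feature_table(recs, model_config("acc", "general"),
                             features = fz)
  gps <- build_feature_table(recs, model_config("acc_gps", "general"),
                             features = fz)
  expect_true(all(c("gps_avg_speed", "gps_elev_diff") %in% names(gps)))
  expect_length(attr(gps, "feature_names"), 427)
  expect_equal(nrow(gps) + attr(gps, "gps_dropped"), nrow(acc))
  expect_false(anyNA(gps$gps_avg_speed))
})

test_that("subjects missing a required position are excluded with a warning", {
  recs <- tiny_cohorts()
  partial <- recs[[1]]
  partial$acc <- partial$acc["chest"]
  mixed <- c(list(partial), recs[2:3])
  expect_warning(
    tbl <- build_feature_table(mixed, model_config("acc", "general")),
    "lack position")
  expect_false(recs[[1]]$subject_id %in% tbl$subject_id)
})

test_that("training on a separable toy problem reaches perfect accuracy", {
  tbl <- toy_table()
  cfg <- model_config("acc", "individual:chest", n_trees = 50, seed = 3)
  model <- train_patd(tbl, cfg)
  expect_s3_class(model, "patd_model")
  expect_setequal(model$classes, c("walking", "running"))
  expect_equal(predict_patd(model, tbl), tbl$label)
})

test_that("training is deterministic given the seed", {
  tbl <- toy_table(seed = 2)
  cfg <- model_config("acc", "individual:chest", n_trees = 50, seed = 11)
  m1 <- train_patd(tbl, cfg)
  m2 <- train_patd(tbl, cfg)
  expect_identical(m1$fit$prediction.error, m2$fit$prediction.error)
  expect_identical(predict_patd(m1, tbl), predict_patd(m2, tbl))
})

test_that("single-class tables are rejected", {
  tbl <- toy_table()
  tbl$label <- "walking"
  expect_error(train_patd(tbl, model_config("acc", "individual:chest")),
               "at least 2 classes")
})

test_that("prediction aligns columns by name, not order", {
  tbl <- toy_table()
  cfg <- model_config("acc", "individual:chest", n_trees = 50, seed = 5)
  model <- train_patd(tbl, cfg)
  shuffled <- tbl[, c("f_b", "label", "f_a", "subject_id", "cohort",
                      "protocol", "position", "t_start"), with = FALSE]
  data.table::setattr(shuffled, "feature_names", c("f_b", "f_a"))
  expect_identical(predict_patd(model, shuffled), predict_patd(model, tbl))
})

test_that("feature schema mismatches are hard errors naming the offenders", {
  tbl <- toy_table()
  model <- train_patd(tbl, model_config("acc", "individual:chest", n_trees = 20))
  missing_col <- data.table::copy(tbl)[, "f_b" := NULL]
  data.table::setattr(missing_col, "feature_names", "f_a")
  expect_error(predict_patd(model, missing_col), "missing \\[f_b\\]")
  extra_col <- data.table::copy(tbl)[, "f_c" := 1]
  data.table::setattr(extra_col, "feature_names", c("f_a", "f_b", "f_c"))
  expect_error(predict_patd(model, extra_col), "extra \\[f_c\\]")
})

test_that("predicting on an empty table returns an empty vector", {
  tbl <- toy_table()
  model <- train_patd(tbl, model_config("acc", "individual:chest", n_trees = 20))
  expect_identical(predict_patd(model, tbl[0, ]), character(0))
})

test_that("models round-trip through save/load; version gate works", {
  tbl <- toy_table()
  model <- train_patd(tbl, model_config("acc", "individual:chest", n_trees = 20))
  path <- withr::local_tempfile(fileext = ".rds")
  save_patd_model(model, path)
  back <- load_patd_model(path)
  expect_identical(predict_patd(back, tbl), predict_patd(model, tbl))
  stale <- model
  stale$package_version <- "99.0.0"
  saveRDS(stale, path)
  expect_error(load_patd_model(path), "refusing to load")
})

test_that("featurize_dataset output matches segment + acc_features", {
  recs <- tiny_cohorts()[1]
  fz <- featurize_dataset(recs)
  wins <- segment(recs[[1]], "chest")
  wins <- Filter(function(w) !is.na(w$label), wins)
  w <- wins[[5]]
  row <- fz$acc[fz$acc$subject_id == w$subject_id &
                  fz$acc$position == "chest" & fz$acc$t_start == w$t_start, ]
  expect_equal(nrow(row), 1)
  expect_equal(unlist(row[, acc_feature_names(), with = FALSE]),
               acc_features(w$acc_block), tolerance = 1e-12)
  expect_identical(row$label, w$label)
})
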