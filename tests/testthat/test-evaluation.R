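test_that("scenario and age-design registries resolve and reject unknowns", {
  s <- scenario_spec("S1B")
  expect_equal(s$train_protocols, "semi_structured")
  expect_equal(s$test_protocols, "real_life")
  expect_equal(scenario_spec("S2A")$train_protocols, PATD_PROTOCOLS)
  expect_error(scenario_spec("S4"), "unknown scenario")
  a <- age_model_spec("yando_trained_btw")
  expect_setequal(a$train_cohorts, c("young", "old"))
  expect_equal(a$test_cohort, "old")
  expect_error(age_model_spec("btw"), "unknown age design")
})

test_that("l1so_folds covers every subject exactly once", {
  ids <- c("a", "b", "c", "d")
  folds <- l1so_folds(ids)
  expect_length(folds, 4)
  expect_setequal(vapply(folds, `[[`, "", "test_id"), ids)
  for (f in folds) {
    expect_false(f$test_id %in% f$train_ids)
    expect_setequal(c(f$train_ids, f$test_id), ids)
  }
  expect_error(l1so_folds("only_one"), "at least 2")
})

test_that("f1 arithmetic: harmonic mean, zero convention, vectorized", {
  expect_equal(f1_score(100, 100), 100)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(100, 50), 2 * 100 * 50 / 150)
  expect_equal(f1_score(c(80, 0), c(40, 0)), c(2 * 80 * 40 / 120, 0))
})

test_that("per-class metrics on a diagonal confusion matrix are all 100", {
  cm <- diag(7L * seq_len(6))
  dimnames(cm) <- list(truth = PATD_ACTIVITIES, prediction = PATD_ACTIVITIES)
  pc <- precision_recall_f1(cm)
  expect_equal(pc$precision, rep(100, 6))
  expect_equal(pc$recall, rep(100, 6))
  expect_equal(pc$f1, rep(100, 6))
  expect_equal(overall_accuracy(cm), 100)
})

test_that("per-class metrics match hand tallies on a small matrix", {
  cm <- matrix(0L, 6, 6, dimnames = list(PATD_ACTIVITIES, PATD_ACTIVITIES))
  cm["walking", "walking"] <- 8
  cm["walking", "running"] <- 2
  cm["running", "walking"] <- 3
  cm["running", "running"] <- 7
  pc <- precision_recall_f1(cm)
  w <- pc[pc$class == "walking", ]
  expect_equal(w$precision, 100 * 8 / 11)
  expect_equal(w$recall, 100 * 8 / 10)
  expect_equal(w$f1, f1_score(100 * 8 / 11, 80))
  # absent classes: all-zero rows/columns give 0 by convention
  expect_equal(pc$f1[pc$class == "lying"], 0)
  expect_equal(overall_accuracy(cm), 100 * 15 / 20)
  expect_error(overall_accuracy(empty_6x6 <- cm * 0L), "empty")
})

test_that("confusion_pair_rate counts mutual confusions only", {
  cm <- matrix(0L, 6, 6, dimnames = list(PATD_ACTIVITIES, PATD_ACTIVITIES))
  cm["walking", "walking"] <- 6
  cm["walking", "running"] <- 4
  cm["running", "running"] <- 9
  cm["running", "sitting"] <- 1    # not a run/walk confusion
  expect_equal(confusion_pair_rate(cm, "running", "walking"), 100 * 4 / 20)
  expect_equal(confusion_pair_rate(cm, "running", "walking"),
               confusion_pair_rate(cm, "walking", "running"))
  expect_equal(confusion_pair_rate(cm, "lying", "sitting"), 0)
  expect_error(confusion_pair_rate(cm, "walking", "walking"))
})

test_that("confusion_matrix places truth in rows, predictions in columns", {
  cm <- confusion_matrix(c("walking", "walking"), c("walking", "running"))
  expect_equal(cm["walking", "running"], 1L)
  expect_equal(cm["running", "walking"], 0L)
  expect_equal(sum(cm), 2L)
})

test_that("run_design: no leakage and correct partitioning on every fold", {
  recs <- tiny_cohorts()
  fz <- tiny_features()
  cfg <- model_config("acc", "individual:right_knee", n_trees = 25, seed = 1)
  tbl <- build_feature_table(recs, cfg, features = fz)
  for (sc in c("S1A", "S1B", "S2A", "S2B", "S3A")) {
    for (ad in c("within_old", "within_young", "y_trained_btw",
                 "yando_trained_btw")) {
      rep <- run_design(tbl, sc, ad, cfg)
      spec_s <- scenario_spec(sc); spec_a <- age_model_spec(ad)
      test_cohort_ids <- unique(tbl$subject_id[tbl$cohort == spec_a$test_cohort])
      expect_setequal(names(rep$folds), test_cohort_ids)
      for (f in rep$folds) {
        expect_false(f$test_id %in% f$train_subjects)
        train_cohorts <- unique(tbl$cohort[tbl$subject_id %in% f$train_subjects])
        expect_true(all(train_cohorts %in% spec_a$train_cohorts))
      }
      expect_equal(sum(rep$confusion),
                   sum(tbl$cohort == spec_a$test_cohort &
                         tbl$protocol %in% spec_s$test_protocols))
    }
  }
})

test_that("run_design window accounting differs between S1A and S1B", {
  recs <- tiny_cohorts()
  fz <- tiny_features()
  cfg <- model_config("acc", "individual:chest", n_trees = 25, seed = 1)
  tbl <- build_feature_table(recs, cfg, features = fz)
  r_semi <- run_design(tbl, "S1A", "within_young", cfg)
  r_real <- run_design(tbl, "S1B", "within_young", cfg)
  n_semi <- sum(tbl$cohort == "young" & tbl$protocol == "semi_structured")
  n_real <- sum(tbl$cohort == "young" & tbl$protocol == "real_life")
  expect_equal(sum(r_semi$confusion), n_semi)
  expect_equal(sum(r_real$confusion), n_real)
})

test_that("run_design errors when the test cohort is too small", {
  recs <- tiny_cohorts()
  young_only <- Filter(function(r) r$cohort == "young", recs)
  cfg <- model_config("acc", "individual:chest", n_trees = 10, seed = 1)
  tbl <- build_feature_table(young_only, cfg)
  expect_error(run_design(tbl, "S1A", "within_old", cfg), ">= 2 subjects")
})

test_that("write_report emits json, csv and txt", {
  recs <- tiny_cohorts()
  cfg <- model_config("acc", "individual:chest", n_trees = 10, seed = 1)
  tbl <- build_feature_table(recs, cfg, features = tiny_features())
  rep <- run_design(tbl, "S1A", "within_young", cfg)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_setequal(list.files(dir), c("report.json", "confusion.csv", "report.txt"))
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(js$overall_accuracy, rep$overall_accuracy)
  cm <- data.table::fread(file.path(dir, "confusion.csv"))
  expect_equal(sum(cm[, -1]), sum(rep$confusion))
})
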