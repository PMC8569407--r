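# Small programmatic fixtures shared across test files. Generation is cheap
# but not free, so cohort fixtures are cached per test session.

short_schedules <- function() {
  list(
    semi_structured = data.table::data.table(
      activity = c("lying", "sitting", "standing", "walking",
                   "nonlevel_walking", "running"),
      duration_s = c(12, 12, 12, 20, 20, 16)),
    real_life = data.table::data.table(
      activity = c("sitting", "walking", "standing", "nonlevel_walking",
                   "running", "lying"),
      duration_s = c(12, 16, 12, 16, 16, 12)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# 3 young + 3 old subjects on compact schedules: enough for structural tests
tiny_cohorts <- function() {
  cached("tiny_cohorts", {
    prof <- default_profiles()
    c(generate_cohort(3, prof$young, schedules = short_schedules(), seed = 401),
      generate_cohort(3, prof$old, schedules = short_schedules(), seed = 402))
  })
}

tiny_features <- function() {
  cached("tiny_features", featurize_dataset(tiny_cohorts()))
}

# a regular 50 Hz accelerometer stream of constant values
flat_stream <- function(subject = "s1", duration = 10, fs = 50, value = c(0, 0, 1)) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  acc_stream(subject, "chest", t, rep(value[1], length(t)),
             rep(value[2], length(t)), rep(value[3], length(t)))
}

simple_record <- function(subject = "s1", duration = 10, activity = "standing",
                          protocol = "semi_structured") {
  acc <- flat_stream(subject, duration)
  labs <- label_track(subject, 0, duration, activity, protocol)
  subject_record(subject, "young", list(chest = acc), labs)
}
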