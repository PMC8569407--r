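test_that("feature name contract: 85 unique names in fixed order", {
  nm <- acc_feature_names()
  expect_length(nm, 85)
  expect_false(anyDuplicated(nm) > 0)
  expect_identical(nm[1:4], c("mean_x", "mean_y", "mean_z", "mean_total"))
  expect_identical(nm[85], "domfreq_total")
  expect_identical(nm[13:15], c("corr_xy", "corr_xz", "corr_yz"))
})

test_that("total acceleration on known triples", {
  expect_equal(total_acceleration(0, 0, 1), 1)
  expect_equal(total_acceleration(3, 4, 0), 5)
  expect_equal(total_acceleration(c(1, 0), c(0, 1), c(0, 0)), c(1, 1))
  expect_error(total_acceleration(1:3, 1:2, 1:3))
})

test_that("constant block follows the zero-variance conventions", {
  n <- 100
  block <- list(t = seq(0, 1.98, by = 0.02),
                ax = rep(0.5, n), ay = rep(-0.25, n), az = rep(1, n))
  f <- acc_features(block)
  expect_equal(unname(f["mean_x"]), 0.5)
  expect_equal(unname(f["mean_total"]), sqrt(0.5^2 + 0.25^2 + 1))
  expect_equal(unname(f[c("sd_x", "sd_y", "sd_z", "sd_total")]), rep(0, 4))
  expect_equal(unname(f[c("range_x", "range_total")]), c(0, 0))
  expect_equal(unname(f[c("corr_xy", "corr_xz", "corr_yz")]), rep(0, 3))
  expect_equal(unname(f[c("kurtosis_x", "skewness_x", "aad_x")]), rep(0, 3))
  # all samples land in the first histogram bin when min == max
  expect_equal(unname(f["hist_x_1"]), n)
  expect_equal(sum(f[sprintf("hist_x_%d", 2:10)]), 0)
  # no peaks on a flat line
  expect_equal(unname(f[c("peak_count_x", "peak_interval_x")]), c(0, 0))
  # constant signal: positive-frequency spectrum identically zero
  expect_equal(sum(abs(f[61:85])), 0)
})

test_that("histogram counts always sum to n and match oracle", {
  for (seed in 1:5) {
    b <- random_block(seed = seed)
    f <- time_domain_features(b)
    for (ax in c("x", "y", "z")) {
      expect_equal(sum(f[sprintf("hist_%s_%d", ax, 1:10)]), length(b$t))
    }
    expect_equal(unname(f[sprintf("hist_x_%d", 1:10)]),
                 as.numeric(oracle_hist10(b$ax)))
  }
})

test_that("2 Hz sinusoid has 4 peaks / 0.5 s spacing in a 2 s window", {
  t <- seq(0, 1.98, by = 0.02)
  block <- list(t = t, ax = sin(2 * pi * 2 * t), ay = t * 0, az = t * 0 + 1)
  f <- time_domain_features(block)
  expect_equal(unname(f["peak_count_x"]), 4)
  expect_equal(unname(f["peak_interval_x"]), 0.5, tolerance = 0.02)
})

test_that("5 Hz sine yields dominant frequency exactly 5 Hz", {
  t <- seq(0, 1.98, by = 0.02)  # n = 100, bin width 0.5 Hz
  block <- list(t = t, ax = sin(2 * pi * 5 * t), ay = t * 0, az = t * 0)
  f <- freq_domain_features(block, fs_hz = 50)
  # x dominates at 5 Hz: amplitude |X|/n = 0.5 for a unit sine on-bin
  expect_equal(unname(f["domamp_x_1"]), 0.5, tolerance = 1e-12)
  sp <- patd:::one_sided_spectrum(block$ax, 50)
  expect_equal(sp$freq[which.max(sp$amp)], 5)
})

test_that("Parseval-style identity links psd, energy and bin count", {
  b <- random_block(seed = 42)
  f <- freq_domain_features(b, fs_hz = 50)
  sp <- patd:::one_sided_spectrum(b$ax, 50)
  kmax <- length(b$ax) %/% 2
  expect_equal(unname(f["energy_x"]), sum(sp$amp^2) / kmax, tolerance = 1e-12)
  expect_equal(unname(f["psd_x"]),
               sum(sp$amp^2) * length(b$ax) / 50, tolerance = 1e-12)
})

test_that("axis permutation equivariance of per-axis features", {
  b <- random_block(seed = 7)
  f1 <- acc_features(list(t = b$t, ax = b$ax, ay = b$ay, az = b$az))
  f2 <- acc_features(list(t = b$t, ax = b$ay, ay = b$ax, az = b$az))
  for (stat in c("mean", "sd", "range", "kurtosis", "skewness", "aad",
                 "peak_count", "peak_interval", "energy", "domfreq_mean",
                 "psd")) {
    expect_equal(unname(f1[paste0(stat, "_x")]), unname(f2[paste0(stat, "_y")]),
                 info = stat)
    expect_equal(unname(f1[paste0(stat, "_y")]), unname(f2[paste0(stat, "_x")]))
  }
  expect_equal(unname(f1["corr_xy"]), unname(f2["corr_xy"]))
  expect_equal(unname(f1["corr_xz"]), unname(f2["corr_yz"]))
  expect_equal(unname(f1["mean_total"]), unname(f2["mean_total"]))
})

test_that("features are invariant to a time-origin shift", {
  b <- random_block(seed = 11)
  f1 <- acc_features(list(t = b$t, ax = b$ax, ay = b$ay, az = b$az))
  f2 <- acc_features(list(t = b$t + 1234.5, ax = b$ax, ay = b$ay, az = b$az))
  expect_equal(f1, f2)
})

test_that("all 85 features match the naive oracles on random windows", {
  for (seed in c(1, 2, 3)) {
    b <- random_block(seed = seed)
    f <- acc_features(list(t = b$t, ax = b$ax, ay = b$ay, az = b$az))
    expect_length(f, 85)
    expect_identical(names(f), acc_feature_names())
    expect_true(all(is.finite(f)))
    oracle <- c(oracle_time_features(b$t, b$ax, b$ay, b$az),
                oracle_freq_features(b$ax, b$ay, b$az, 50))
    expect_equal(unname(f), oracle, tolerance = 1e-9)
  }
})

test_that("blocks work as data.frame, data.table or plain list", {
  b <- random_block(seed = 3)
  as_list <- acc_features(b)
  as_df <- acc_features(as.data.frame(b))
  as_dt <- acc_features(data.table::as.data.table(b))
  expect_equal(as_list, as_df)
  expect_equal(as_list, as_dt)
})

test_that("peak rule details: prominence and separation filters", {
  # two bumps 0.1 s apart: only the taller survives the 0.2 s separation
  t <- seq(0, 1.98, by = 0.02)
  x <- numeric(100)
  x[20] <- 1; x[25] <- 0.8                     # 0.38 s and 0.48 s
  expect_equal(patd:::find_peaks(x, t), t[20])
  # a bump below the prominence threshold is ignored
  y <- numeric(100); y[50] <- 0.04
  expect_length(patd:::find_peaks(y, t), 0)
  # plateau (non-strict maximum) is not a peak
  z <- numeric(100); z[40:41] <- 1
  expect_length(patd:::find_peaks(z, t), 0)
})
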