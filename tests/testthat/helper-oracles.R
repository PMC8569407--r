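# Independent, deliberately naive reference implementations used to verify
# the package's feature computations. Everything here is written as plain
# loops / direct definitions and shares no code with the package internals.

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_range <- function(x) max(x) - min(x)

oracle_cor <- function(a, b) {
  if (oracle_sd(a) == 0 || oracle_sd(b) == 0) return(0)
  ma <- oracle_mean(a); mb <- oracle_mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

oracle_kurtosis <- function(x) {
  m <- oracle_mean(x)
  m2 <- oracle_mean((x - m)^2)
  if (m2 == 0) return(0)
  oracle_mean((x - m)^4) / m2^2 - 3
}

oracle_skewness <- function(x) {
  m <- oracle_mean(x)
  m2 <- oracle_mean((x - m)^2)
  if (m2 == 0) return(0)
  oracle_mean((x - m)^3) / m2^1.5
}

oracle_aad <- function(x) oracle_mean(abs(x - oracle_mean(x)))

oracle_hist10 <- function(x) {
  lo <- min(x); hi <- max(x)
  counts <- integer(10)
  if (hi == lo) { counts[1] <- length(x); return(counts) }
  w <- (hi - lo) / 10
  for (v in x) {
    b <- 1L
    while (b < 10L && v >= lo + b * w) b <- b + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

# Peak rule, re-derived from its documentation: strict local maxima;
# prominence = height minus the higher of the two base minima, each base
# being the lowest value seen while walking away from the peak until a
# strictly higher sample or the edge; prominence filter, then greedy
# acceptance by descending height with a minimum time separation.
oracle_peaks <- function(x, t, sep_min = 0.2, prom_min = 0.05) {
  n <- length(x)
  cand <- c()
  for (i in seq_len(n)) {
    if (i > 1 && i < n && x[i] > x[i - 1] && x[i] > x[i + 1]) cand <- c(cand, i)
  }
  keep_prom <- c()
  for (i in cand) {
    lmin <- Inf
    for (j in (i - 1):1) {
      if (x[j] > x[i]) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- Inf
    for (j in (i + 1):n) {
      if (x[j] > x[i]) break
      if (x[j] < rmin) rmin <- x[j]
    }
    if (x[i] - max(lmin, rmin) >= prom_min) keep_prom <- c(keep_prom, i)
  }
  if (!length(keep_prom)) return(numeric(0))
  ord <- keep_prom[order(-x[keep_prom], keep_prom)]
  kept <- c()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) if (abs(t[i] - t[k]) < sep_min) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  sort(t[kept])
}

oracle_time_features <- function(t, ax, ay, az) {
  tot <- sqrt(ax^2 + ay^2 + az^2)
  sigs <- list(ax, ay, az, tot)
  axes <- list(ax, ay, az)
  out <- c(
    sapply(sigs, oracle_mean), sapply(sigs, oracle_sd),
    sapply(sigs, oracle_range),
    oracle_cor(ax, ay), oracle_cor(ax, az), oracle_cor(ay, az),
    sapply(axes, oracle_kurtosis), sapply(axes, oracle_skewness),
    sapply(axes, oracle_aad),
    unlist(lapply(axes, oracle_hist10)),
    sapply(axes, function(s) {
      p <- oracle_peaks(s, t)
      if (length(p) >= 2) oracle_mean(diff(p)) else 0
    }),
    sapply(axes, function(s) length(oracle_peaks(s, t))))
  unname(out)
}

# Direct O(n^2) DFT; one-sided normalized magnitudes for bins 1..floor(n/2).
oracle_dft_amp <- function(x) {
  n <- length(x)
  kmax <- n %/% 2
  amp <- numeric(kmax)
  for (k in seq_len(kmax)) {
    re <- 0; im <- 0
    for (j in seq_len(n)) {
      ang <- -2 * pi * k * (j - 1) / n
      re <- re + x[j] * cos(ang)
      im <- im + x[j] * sin(ang)
    }
    amp[k] <- sqrt(re^2 + im^2) / n
  }
  amp
}

oracle_freq_features_one <- function(x, fs) {
  n <- length(x)
  amp <- oracle_dft_amp(x)
  freq <- seq_along(amp) * fs / n
  if (max(amp) == 0) return(c(0, 0, 0, 0, 0, 0, 0))
  ord <- order(-amp, freq)[1:3]
  c(oracle_mean(amp^2), oracle_mean(freq[ord]),
    amp[ord[1]], amp[ord[2]], amp[ord[3]],
    sum(amp^2) * n / fs, freq[ord[1]])
}

oracle_freq_features <- function(ax, ay, az, fs) {
  tot <- sqrt(ax^2 + ay^2 + az^2)
  per <- lapply(list(ax, ay, az, tot), oracle_freq_features_one, fs = fs)
  c(unlist(lapply(per, function(p) p[1:6])), per[[4]][7])
}

oracle_haversine <- function(lat1, lon1, lat2, lon2, r = 6371000) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(a))
}

# random window block resembling locomotion data
random_block <- function(n = 100, fs = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, by = 1 / fs, length.out = n)
  f <- runif(1, 0.8, 4)
  list(t = t,
       ax = 0.1 * sin(2 * pi * f * t) + rnorm(n, 0, 0.1),
       ay = rnorm(n, 0.1, 0.15),
       az = 1 + 0.4 * sin(2 * pi * f * t + 1) + rnorm(n, 0, 0.1))
}
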