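## 85 time- and frequency-domain features per 2 s tri-axial window.
##
## Inventory (order is the package contract, see acc_feature_names()):
##   time domain (60):
##     mean, sd, range of x, y, z and total acceleration          12
##     pairwise axis correlations xy, xz, yz                       3
##     excess kurtosis, skewness, average absolute difference
##       of x, y, z                                                9
##     10-bin equal-width histogram counts of x, y, z             30
##     mean inter-peak interval (s) and peak count of x, y, z      6
##   frequency domain (25):
##     per signal (x, y, z, total): signal energy, mean of the
##       three dominant frequencies, amplitudes of the three
##       dominant frequencies, total spectral power density       24
##     dominant frequency of the total-acceleration signal         1
##
## Conventions fixed for reproducibility: sd uses the n-1 denominator;
## kurtosis is excess kurtosis from population moments; correlations,
## kurtosis and skewness of a zero-variance signal are 0; histogram bins
## span [window min, window max] with the right-most bin closed; spectra use
## the raw block (no detrend/taper), one-sided magnitudes |X_k|/n with DC
## excluded from dominant-frequency search.

#' Feature-name contract
#'
#' The 85 accelerometer feature names in their fixed emission order. This
#' order is part of the package contract: feature tables and trained models
#' key columns by these names.
#'
#' @return Character vector of length 85.
#' @export
acc_feature_names <- function() {
  sigs <- c("x", "y", "z", "total")
  axes <- c("x", "y", "z")
  c(paste0("mean_", sigs), paste0("sd_", sigs), paste0("range_", sigs),
    paste0("corr_", c("xy", "xz", "yz")),
    paste0("kurtosis_", axes), paste0("skewness_", axes), paste0("aad_", axes),
    paste0("hist_", rep(axes, each = 10), "_", rep(1:10, 3)),
    paste0("peak_interval_", axes), paste0("peak_count_", axes),
    as.vector(vapply(sigs, function(s)
      c(paste0("energy_", s), paste0("domfreq_mean_", s),
        paste0("domamp_", s, "_", 1:3), paste0("psd_", s)),
      character(6))),
    "domfreq_total")
}

#' Per-sample total acceleration
#'
#' Euclidean norm of the three acceleration axes, treated as a fourth signal
#' for feature extraction. For a resting posture it centers near 1 g.
#'
#' @param ax,ay,az Numeric acceleration vectors in g.
#' @return Numeric vector of per-sample magnitudes.
#' @export
total_acceleration <- function(ax, ay, az) {
  stopifnot(length(ax) > 0, length(ax) == length(ay), length(ax) == length(az))
  sqrt(ax^2 + ay^2 + az^2)
}

## population central moments; zero-variance convention -> 0
moment_stat <- function(x, pow) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mk <- mean((x - mean(x))^pow)
  if (pow == 3L) mk / m2^1.5 else mk / m2^2 - 3
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

hist_counts10 <- function(x) {
  lo <- min(x); w <- (max(x) - lo) / 10
  if (w == 0) return(c(length(x), rep(0L, 9L)))
  idx <- pmin(floor((x - lo) / w) + 1L, 10L)  # right-most bin closed
  tabulate(idx, nbins = 10L)
}

## Peak rule: a candidate is a strict local maximum (greater than both
## neighbours; endpoints excluded). Its prominence is the drop to the higher
## of the two bases, where each base is the minimum value encountered while
## extending from the peak until a strictly higher sample or the block edge.
## Candidates below `prominence_min` are discarded; the rest are accepted
## greedily by descending height (ties: earlier first) subject to a minimum
## time separation `sep_min_s` from every already-accepted peak.
find_peaks <- function(x, t, sep_min_s = 0.2, prominence_min = 0.05) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    j <- i - 1L; lmin <- x[j]
    while (j > 1L && x[j] <= x[i]) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    if (x[j] <= x[i] && x[j] < lmin) lmin <- x[j]
    k <- i + 1L; rmin <- x[k]
    while (k < n && x[k] <= x[i]) { if (x[k] < rmin) rmin <- x[k]; k <- k + 1L }
    if (x[k] <= x[i] && x[k] < rmin) rmin <- x[k]
    x[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= prominence_min]
  if (!length(cand)) return(numeric(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(t[i] - t[kept]) >= sep_min_s)) kept <- c(kept, i)
  }
  sort(t[kept])
}

#' Time-domain features of one window (60 values)
#'
#' @param block A data.frame/data.table with columns `t`, `ax`, `ay`, `az`
#'   (one accelerometer window, >= 4 samples).
#' @param peak_sep_s Minimum separation between accepted peaks, seconds.
#' @param peak_prominence_min Minimum peak prominence, g.
#' @return Named numeric vector of length 60 (see [acc_feature_names()]).
#' @export
time_domain_features <- function(block, peak_sep_s = 0.2,
                                 peak_prominence_min = 0.05) {
  ax <- block$ax; ay <- block$ay; az <- block$az; t <- block$t
  stopifnot(length(ax) >= 4L)
  tot <- total_acceleration(ax, ay, az)
  sigs <- list(x = ax, y = ay, z = az, total = tot)
  axes <- sigs[1:3]

  peaks <- lapply(axes, find_peaks, t = t, sep_min_s = peak_sep_s,
                  prominence_min = peak_prominence_min)
  ipi <- vapply(peaks, function(p) if (length(p) >= 2L) mean(diff(p)) else 0,
                numeric(1))

  out <- c(
    vapply(sigs, mean, numeric(1)),
    vapply(sigs, stats::sd, numeric(1)),
    vapply(sigs, function(s) max(s) - min(s), numeric(1)),
    safe_cor(ax, ay), safe_cor(ax, az), safe_cor(ay, az),
    vapply(axes, moment_stat, numeric(1), pow = 4L),
    vapply(axes, moment_stat, numeric(1), pow = 3L),
    vapply(axes, function(s) mean(abs(s - mean(s))), numeric(1)),
    unlist(lapply(axes, hist_counts10)),
    ipi,
    vapply(peaks, length, integer(1)))
  names(out) <- acc_feature_names()[1:60]
  out
}

## One-sided normalized magnitude spectrum: |fft(x)[k]| / n for the positive
## frequency bins k = 1..floor(n/2) (DC excluded, Nyquist included for even n).
one_sided_spectrum <- function(x, fs_hz) {
  n <- length(x)
  kmax <- n %/% 2L
  amp <- Mod(stats::fft(x))[2:(kmax + 1L)] / n
  list(freq = (1:kmax) * fs_hz / n, amp = amp)
}

spectral_features_one <- function(x, fs_hz) {
  sp <- one_sided_spectrum(x, fs_hz)
  ## a constant signal has a mathematically zero positive spectrum, but the
  ## FFT leaves ~1e-16-relative rounding residue; treat it as zero
  if (max(sp$amp) <= 1e-12 * mean(abs(x))) {
    return(c(energy = 0, domfreq_mean = 0, domamp1 = 0, domamp2 = 0,
             domamp3 = 0, psd = 0, domfreq1 = 0))
  }
  ord <- order(-sp$amp, sp$freq)[1:3]   # ties broken toward lower frequency
  c(energy = mean(sp$amp^2),
    domfreq_mean = mean(sp$freq[ord]),
    domamp1 = sp$amp[ord[1]], domamp2 = sp$amp[ord[2]], domamp3 = sp$amp[ord[3]],
    psd = sum(sp$amp^2) * length(x) / fs_hz,
    domfreq1 = sp$freq[ord[1]])
}

#' Frequency-domain features of one window (25 values)
#'
#' FFT-based features of the raw (undetrended, untapered) block: per signal
#' (x, y, z, total acceleration) the signal energy (mean squared one-sided
#' normalized magnitude over positive frequencies), the mean of the three
#' dominant frequencies (largest-amplitude positive-frequency bins, DC
#' excluded, ties toward lower frequency), the amplitudes of those three
#' bins in descending order, and the total spectral power density
#' (sum of squared magnitudes divided by the bin width fs/n); plus, as the
#' 25th feature, the dominant frequency of the total-acceleration signal.
#' A signal whose positive-frequency spectrum is zero up to FFT rounding
#' (a constant signal) gets all its spectral features set to 0.
#'
#' @param block Window block as in [time_domain_features()].
#' @param fs_hz Sampling rate in Hz.
#' @return Named numeric vector of length 25.
#' @export
freq_domain_features <- function(block, fs_hz = 50) {
  ax <- block$ax; ay <- block$ay; az <- block$az
  stopifnot(fs_hz > 0, length(ax) >= 8L)
  sigs <- list(x = ax, y = ay, z = az,
               total = total_acceleration(ax, ay, az))
  per <- lapply(sigs, spectral_features_one, fs_hz = fs_hz)
  out <- c(unlist(lapply(per, function(p) p[1:6]), use.names = FALSE),
           per$total[["domfreq1"]])
  names(out) <- acc_feature_names()[61:85]
  out
}

#' All 85 accelerometer features of one window
#'
#' Concatenation of [time_domain_features()] and [freq_domain_features()] in
#' the contract order of [acc_feature_names()].
#'
#' @inheritParams time_domain_features
#' @inheritParams freq_domain_features
#' @return Named numeric vector of length 85, all finite.
#' @export
acc_features <- function(block, fs_hz = 50, peak_sep_s = 0.2,
                         peak_prominence_min = 0.05) {
  c(time_domain_features(block, peak_sep_s, peak_prominence_min),
    freq_domain_features(block, fs_hz))
}
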