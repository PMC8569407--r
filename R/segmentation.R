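## Overlapping fixed-length windowing of aligned streams.
## Windows use half-open intervals [t_start, t_start + window_len) on the
## shared session clock, starting at the stream's first sample and advancing
## by `step_s`. A window is emitted only when it holds at least
## `min_fill_frac` of the nominal sample count (80 samples for 2 s at 50 Hz
## with the defaults), so dropouts suppress windows instead of producing
## short feature blocks.

#' Default segmentation configuration
#'
#' @param window_len_s Window length in seconds (default 2).
#' @param step_s Step between window starts in seconds (default 1, i.e. 50%
#'   overlap between consecutive windows).
#' @param purity_min Minimum fraction of the window covered by a single
#'   activity for the window to receive that label (default 0.8); windows
#'   below it (e.g. activity transitions) are excluded from training/testing.
#' @param min_fill_frac Minimum fraction of the nominal sample count a window
#'   must contain to be emitted (default 0.8).
#' @param fs_hz Nominal accelerometer sampling rate in Hz (default 50).
#' @return A named list of segmentation parameters.
#' @export
segmentation_config <- function(window_len_s = 2, step_s = 1, purity_min = 0.8,
                                min_fill_frac = 0.8, fs_hz = 50) {
  stopifnot(window_len_s > 0, step_s > 0, step_s <= window_len_s,
            purity_min > 0.5, purity_min <= 1,
            min_fill_frac > 0, min_fill_frac <= 1, fs_hz > 0)
  list(window_len_s = window_len_s, step_s = step_s, purity_min = purity_min,
       min_fill_frac = min_fill_frac, fs_hz = fs_hz)
}

## Candidate window starts and per-window sample counts for one time vector.
## Returns data.table(t_start, i0, i1, n) with [i0, i1] the index range of
## samples falling in [t_start, t_start + window_len).
window_index <- function(t, window_len_s, step_s) {
  if (length(t) == 0L) {
    return(data.table::data.table(t_start = numeric(), i0 = integer(),
                                  i1 = integer(), n = integer()))
  }
  t0 <- t[1L]
  t_last <- t[length(t)]
  n_starts <- if (t_last - t0 < step_s) 1L else floor((t_last - t0) / step_s) + 1L
  starts <- t0 + (seq_len(n_starts) - 1L) * step_s
  starts <- starts[starts < t_last | seq_along(starts) == 1L]
  ## samples in [s, s + L): t >= s and t < s + L
  i0 <- findInterval(starts, t, left.open = TRUE) + 1L          # first t >= s
  i1 <- findInterval(starts + window_len_s, t, left.open = TRUE) # last t < s + L
  data.table::data.table(t_start = starts, i0 = i0, i1 = i1,
                         n = pmax(i1 - i0 + 1L, 0L))
}

#' Cut one position's streams into overlapping labeled windows
#'
#' Splits the accelerometer stream of `position` into windows of
#' `window_len_s` seconds starting every `step_s` seconds from the stream's
#' first sample, attaching co-temporal GPS fixes and (optionally) an activity
#' label via [assign_label()]. Windows with fewer than
#' `min_fill_frac * window_len_s * fs_hz` samples (e.g. overlapping a sensor
#' dropout) are suppressed. An empty stream yields an empty list.
#'
#' @param record A [subject_record()].
#' @param position Device position to segment.
#' @param config A [segmentation_config()].
#' @param label Assign activity labels from the record's label track
#'   (default `TRUE`); unlabelable windows get label `NA`.
#' @return List of `patd_window` objects with fields `subject_id`, `cohort`,
#'   `protocol`, `position`, `t_start`, `duration`, `acc_block` (data.table
#'   `t, ax, ay, az`), `gps_fixes` (data.table `t, lat, lon, elev`, possibly
#'   empty) and `label` (activity or `NA`).
#' @export
segment <- function(record, position, config = segmentation_config(),
                    label = TRUE) {
  stopifnot(inherits(record, "subject_record"))
  if (!position %in% names(record$acc)) {
    stop(sprintf("subject '%s' has no accelerometer stream at position '%s'",
                 record$subject_id, position))
  }
  acc <- record$acc[[position]]$data
  idx <- window_index(acc$t, config$window_len_s, config$step_s)
  min_n <- config$min_fill_frac * config$window_len_s * config$fs_hz
  idx <- idx[idx$n >= min_n, ]
  if (nrow(idx) == 0L) return(list())

  lab_info <- if (label) {
    window_labels(idx$t_start, config$window_len_s, record$labels, config$purity_min)
  } else {
    data.table::data.table(activity = rep(NA_character_, nrow(idx)),
                           protocol = rep(NA_character_, nrow(idx)))
  }

  gps <- if (!is.null(record$gps)) record$gps$data else NULL
  out <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    s <- idx$t_start[k]
    fixes <- if (is.null(gps)) {
      data.table::data.table(t = numeric(), lat = numeric(),
                             lon = numeric(), elev = numeric())
    } else {
      gps[gps$t >= s & gps$t < s + config$window_len_s, ]
    }
    out[[k]] <- structure(list(
      subject_id = record$subject_id, cohort = record$cohort,
      protocol = lab_info$protocol[k], position = position,
      t_start = s, duration = config$window_len_s,
      acc_block = acc[idx$i0[k]:idx$i1[k], ],
      gps_fixes = fixes, label = lab_info$activity[k]), class = "patd_window")
  }
  out
}

## Vectorized activity/protocol assignment for many window starts at once.
## For each window the activity covering the largest share of [s, s+L) wins
## iff its share >= purity_min; otherwise NA. With purity_min > 0.5 the
## winner is unique, so the result does not depend on interval ordering.
window_labels <- function(starts, window_len_s, labels, purity_min) {
  stopifnot(inherits(labels, "label_track"), purity_min > 0.5, purity_min <= 1)
  iv <- labels$intervals
  nwin <- length(starts)
  cover <- matrix(0, nrow = nwin, ncol = length(PATD_ACTIVITIES),
                  dimnames = list(NULL, PATD_ACTIVITIES))
  proto <- matrix(0, nrow = nwin, ncol = length(PATD_PROTOCOLS),
                  dimnames = list(NULL, PATD_PROTOCOLS))
  ends <- starts + window_len_s
  for (j in seq_len(nrow(iv))) {
    ovl <- pmax(0, pmin(ends, iv$t_end[j]) - pmax(starts, iv$t_start[j]))
    act <- iv$activity[j]
    cover[, act] <- cover[, act] + ovl
    proto[, iv$protocol[j]] <- proto[, iv$protocol[j]] + ovl
  }
  share <- cover / window_len_s
  best <- max.col(share, ties.method = "first")
  best_share <- share[cbind(seq_len(nwin), best)]
  activity <- ifelse(best_share >= purity_min, PATD_ACTIVITIES[best], NA_character_)
  protocol <- PATD_PROTOCOLS[max.col(proto, ties.method = "first")]
  protocol[is.na(activity)] <- NA_character_
  data.table::data.table(activity = activity, protocol = protocol)
}

#' Assign an activity label to one window
#'
#' Returns the activity covering the largest share of the window's time span
#' if that share is at least `purity_min`, otherwise `NA` (the window is
#' excluded from training and testing). Because `purity_min > 0.5`, the
#' result is independent of the order in which label intervals are listed.
#'
#' @param window A `patd_window` from [segment()].
#' @param labels A [label_track()].
#' @param purity_min Minimum coverage share in (0.5, 1\].
#' @return Activity name, or `NA_character_`.
#' @export
assign_label <- function(window, labels, purity_min = 0.8) {
  window_labels(window$t_start, window$duration, labels, purity_min)$activity
}
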