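## On-disk data model: one directory per subject holding
##   acc_<position>.csv  (t,ax,ay,az)        -- one file per worn device
##   gps.csv             (t,lat,lon,elev)    -- optional
##   labels.csv          (t_start,t_end,activity,protocol)
##   meta.json           (subject_id, cohort, acc_units)
## Timestamps are seconds from session start; acceleration is in g.

NOMINAL_ACC_DT <- 0.02   # 50 Hz
NOMINAL_GPS_DT <- 1.0    # 1 Hz

#' Construct an accelerometer stream
#'
#' A tri-axial accelerometer stream for one device position. Duplicate
#' timestamps are resolved by keeping the first occurrence (with a warning);
#' after deduplication timestamps must be strictly increasing. A warning is
#' also recorded when the median sampling interval deviates more than 10%
#' from the nominal 0.02 s (50 Hz).
#'
#' @param subject_id Subject identifier.
#' @param position One of [PATD_POSITIONS].
#' @param t Numeric timestamps, seconds since session start.
#' @param ax,ay,az Acceleration per axis, in g. Must be finite.
#' @return An object of class `acc_stream`: a list with `subject_id`,
#'   `position` and a `data` data.table (`t`, `ax`, `ay`, `az`).
#' @export
acc_stream <- function(subject_id, position, t, ax, ay, az) {
  position <- match.arg(position, PATD_POSITIONS)
  stopifnot(length(t) == length(ax), length(t) == length(ay),
            length(t) == length(az))
  bad <- which(!is.finite(ax) | !is.finite(ay) | !is.finite(az) | !is.finite(t))
  if (length(bad) > 0L) {
    stop(sprintf("acc_stream '%s'/%s: non-finite values at rows %s",
                 subject_id, position, fmt_rows(bad)))
  }
  dup <- duplicated(t)
  if (any(dup)) {
    warning(sprintf("acc_stream '%s'/%s: %d duplicate timestamps, keeping first",
                    subject_id, position, sum(dup)))
    t <- t[!dup]; ax <- ax[!dup]; ay <- ay[!dup]; az <- az[!dup]
  }
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop(sprintf("acc_stream '%s'/%s: timestamps not strictly increasing at rows %s",
                   subject_id, position, fmt_rows(which(dt <= 0) + 1L)))
    }
    mdt <- stats::median(dt)
    if (abs(mdt - NOMINAL_ACC_DT) > 0.1 * NOMINAL_ACC_DT) {
      warning(sprintf(
        "acc_stream '%s'/%s: median sampling interval %.4fs deviates >10%% from nominal %.2fs",
        subject_id, position, mdt, NOMINAL_ACC_DT))
    }
  }
  structure(list(subject_id = subject_id, position = position,
                 data = data.table::data.table(t = t, ax = ax, ay = ay, az = az)),
            class = "acc_stream")
}

#' Construct a GPS stream
#'
#' @param subject_id Subject identifier.
#' @param t Numeric timestamps (seconds), strictly increasing. Gaps are
#'   permitted and preserved; no interpolation is performed.
#' @param lat,lon Coordinates in degrees (`lat` in \[-90, 90\], `lon` in
#'   \[-180, 180\]).
#' @param elev Elevation in meters.
#' @return An object of class `gps_stream`.
#' @export
gps_stream <- function(subject_id, t, lat, lon, elev) {
  stopifnot(length(t) == length(lat), length(t) == length(lon),
            length(t) == length(elev))
  bad <- which(lat < -90 | lat > 90 | !is.finite(lat))
  if (length(bad)) stop(sprintf("gps_stream '%s': latitude out of [-90, 90] at rows %s",
                                subject_id, fmt_rows(bad)))
  bad <- which(lon < -180 | lon > 180 | !is.finite(lon))
  if (length(bad)) stop(sprintf("gps_stream '%s': longitude out of [-180, 180] at rows %s",
                                subject_id, fmt_rows(bad)))
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop(sprintf("gps_stream '%s': timestamps not strictly increasing at rows %s",
                 subject_id, fmt_rows(which(diff(t) <= 0) + 1L)))
  }
  structure(list(subject_id = subject_id,
                 data = data.table::data.table(t = t, lat = lat, lon = lon, elev = elev)),
            class = "gps_stream")
}

#' Construct a label track
#'
#' Ground-truth activity intervals for one subject. Intervals must be
#' non-overlapping, with `t_start < t_end`, activities drawn from the
#' six-class vocabulary and protocols from the two-protocol vocabulary.
#'
#' @param subject_id Subject identifier.
#' @param t_start,t_end Interval bounds in seconds.
#' @param activity Activity class per interval (see [PATD_ACTIVITIES]).
#' @param protocol Protocol per interval (see [PATD_PROTOCOLS]).
#' @return An object of class `label_track`.
#' @export
label_track <- function(subject_id, t_start, t_end, activity, protocol) {
  stopifnot(length(t_start) == length(t_end),
            length(t_start) == length(activity),
            length(t_start) == length(protocol))
  bad <- which(!activity %in% PATD_ACTIVITIES)
  if (length(bad)) stop(sprintf("label_track '%s': unknown activity %s at rows %s",
                                subject_id, paste(unique(activity[bad]), collapse = ", "),
                                fmt_rows(bad)))
  bad <- which(!protocol %in% PATD_PROTOCOLS)
  if (length(bad)) stop(sprintf("label_track '%s': unknown protocol at rows %s",
                                subject_id, fmt_rows(bad)))
  bad <- which(!(t_start < t_end))
  if (length(bad)) stop(sprintf("label_track '%s': t_start >= t_end at rows %s",
                                subject_id, fmt_rows(bad)))
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]
  activity <- activity[o]; protocol <- protocol[o]
  if (length(t_start) > 1L) {
    ovl <- which(t_start[-1L] < t_end[-length(t_end)])
    if (length(ovl)) stop(sprintf("label_track '%s': overlapping intervals at rows %s",
                                  subject_id, fmt_rows(ovl + 1L)))
  }
  structure(list(subject_id = subject_id,
                 intervals = data.table::data.table(
                   t_start = t_start, t_end = t_end,
                   activity = activity, protocol = protocol)),
            class = "label_track")
}

#' Construct a subject record
#'
#' Bundles one participant's accelerometer streams (one per worn position),
#' optional GPS stream and label track, all sharing one session clock.
#'
#' @param subject_id Subject identifier.
#' @param cohort `"young"` or `"old"`.
#' @param acc Named list of [acc_stream()] objects keyed by position
#'   (1 to 5 entries).
#' @param labels A [label_track()].
#' @param gps Optional [gps_stream()]; `NULL` for accelerometer-only records.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, cohort, acc, labels, gps = NULL) {
  cohort <- match.arg(cohort, c("young", "old"))
  if (length(acc) < 1L) stop(sprintf("subject_record '%s': at least one accelerometer stream required",
                                     subject_id))
  if (is.null(names(acc)) || !all(names(acc) %in% PATD_POSITIONS)) {
    stop(sprintf("subject_record '%s': acc must be a named list keyed by position", subject_id))
  }
  for (p in names(acc)) {
    s <- acc[[p]]
    if (!inherits(s, "acc_stream")) stop("acc entries must be acc_stream objects")
    if (s$subject_id != subject_id || s$position != p) {
      stop(sprintf("subject_record '%s': acc stream '%s' has mismatched subject or position",
                   subject_id, p))
    }
  }
  if (!inherits(labels, "label_track") || labels$subject_id != subject_id) {
    stop(sprintf("subject_record '%s': labels missing or mismatched subject", subject_id))
  }
  if (!is.null(gps) && (!inherits(gps, "gps_stream") || gps$subject_id != subject_id)) {
    stop(sprintf("subject_record '%s': gps stream has mismatched subject", subject_id))
  }
  structure(list(subject_id = subject_id, cohort = cohort,
                 acc = acc[order(match(names(acc), PATD_POSITIONS))],
                 gps = gps, labels = labels),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s cohort)\n", x$subject_id, x$cohort))
  for (p in names(x$acc)) {
    cat(sprintf("  acc %-12s %d samples [%.2f, %.2f] s\n", p,
                nrow(x$acc[[p]]$data), min(x$acc[[p]]$data$t), max(x$acc[[p]]$data$t)))
  }
  if (!is.null(x$gps)) cat(sprintf("  gps %d fixes\n", nrow(x$gps$data)))
  cat(sprintf("  labels: %d intervals, %d activities\n",
              nrow(x$labels$intervals), length(unique(x$labels$intervals$activity))))
  invisible(x)
}

fmt_rows <- function(idx, max_show = 5L) {
  shown <- paste(head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ... (", length(idx), " total)")
  shown
}

## 17 significant digits round-trip IEEE doubles exactly and give byte-stable files
fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(dt, path, num_cols) {
  out <- data.table::copy(dt)
  for (cl in num_cols) data.table::set(out, j = cl, value = fmt_num(out[[cl]]))
  data.table::fwrite(out, path, quote = FALSE, eol = "\n")
  invisible(path)
}

read_csv_checked <- function(path, expected_cols) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, expected_cols)) {
    stop(sprintf("%s: expected header '%s' but found '%s'",
                 basename(path), paste(expected_cols, collapse = ","),
                 paste(hdr, collapse = ",")))
  }
  data.table::fread(path, colClasses = NULL, showProgress = FALSE)
}

#' Write a subject record to disk
#'
#' Emits one directory per subject containing `acc_<position>.csv` per worn
#' device, `gps.csv` (only when GPS is present), `labels.csv` and
#' `meta.json`. Floats are written with 17 significant digits so that
#' [read_subject()] round-trips the record exactly and files are byte-stable.
#'
#' @param record A [subject_record()].
#' @param dir_path Directory to create/write into.
#' @return The directory path, invisibly.
#' @export
write_subject <- function(record, dir_path) {
  stopifnot(inherits(record, "subject_record"))
  if (!dir.exists(dir_path) && !dir.create(dir_path, recursive = TRUE)) {
    stop(sprintf("cannot create directory '%s'", dir_path))
  }
  for (p in names(record$acc)) {
    write_num_csv(record$acc[[p]]$data, file.path(dir_path, paste0("acc_", p, ".csv")),
                  c("t", "ax", "ay", "az"))
  }
  if (!is.null(record$gps)) {
    write_num_csv(record$gps$data, file.path(dir_path, "gps.csv"),
                  c("t", "lat", "lon", "elev"))
  }
  lab <- data.table::copy(record$labels$intervals)
  for (cl in c("t_start", "t_end")) data.table::set(lab, j = cl, value = fmt_num(lab[[cl]]))
  data.table::fwrite(lab, file.path(dir_path, "labels.csv"), quote = FALSE, eol = "\n")
  meta <- list(subject_id = record$subject_id, cohort = record$cohort, acc_units = "g")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir_path, "meta.json"))
  invisible(dir_path)
}

#' Read a subject record from disk
#'
#' Reads the per-subject directory layout written by [write_subject()] and
#' returns a fully validated [subject_record()]. A missing `labels.csv` or
#' `meta.json` is a hard error; a missing `gps.csv` yields a record without
#' GPS (accelerometer-only analyses remain possible). Schema violations are
#' reported naming the offending file; value violations with row numbers.
#'
#' @param dir_path Subject directory.
#' @return A [subject_record()].
#' @export
read_subject <- function(dir_path) {
  if (!dir.exists(dir_path)) stop(sprintf("no such directory: '%s'", dir_path))
  meta_path <- file.path(dir_path, "meta.json")
  if (!file.exists(meta_path)) stop(sprintf("missing meta.json in '%s'", dir_path))
  meta <- jsonlite::fromJSON(meta_path)
  lab_path <- file.path(dir_path, "labels.csv")
  if (!file.exists(lab_path)) stop(sprintf("missing labels.csv in '%s'", dir_path))
  lab <- read_csv_checked(lab_path, c("t_start", "t_end", "activity", "protocol"))
  labels <- label_track(meta$subject_id, lab$t_start, lab$t_end, lab$activity, lab$protocol)

  acc_files <- list.files(dir_path, pattern = "^acc_.*\\.csv$", full.names = TRUE)
  if (!length(acc_files)) stop(sprintf("no accelerometer files in '%s'", dir_path))
  acc <- list()
  for (f in acc_files) {
    pos <- sub("^acc_(.*)\\.csv$", "\\1", basename(f))
    if (!pos %in% PATD_POSITIONS) stop(sprintf("%s: unknown position '%s'", basename(f), pos))
    d <- read_csv_checked(f, c("t", "ax", "ay", "az"))
    acc[[pos]] <- acc_stream(meta$subject_id, pos, d$t, d$ax, d$ay, d$az)
  }

  gps <- NULL
  gps_path <- file.path(dir_path, "gps.csv")
  if (file.exists(gps_path)) {
    d <- read_csv_checked(gps_path, c("t", "lat", "lon", "elev"))
    gps <- gps_stream(meta$subject_id, d$t, d$lat, d$lon, d$elev)
  }
  subject_record(meta$subject_id, meta$cohort, acc, labels, gps)
}

#' Write a list of subject records as a dataset directory
#'
#' @param records List of [subject_record()]s.
#' @param dir_path Dataset root; one subdirectory per subject is created.
#' @return `dir_path`, invisibly.
#' @export
write_dataset <- function(records, dir_path) {
  for (r in records) write_subject(r, file.path(dir_path, r$subject_id))
  invisible(dir_path)
}

#' Read every subject directory under a dataset root
#'
#' @param dir_path Dataset root containing one subdirectory per subject.
#' @return List of [subject_record()]s, named by subject id.
#' @export
read_dataset <- function(dir_path) {
  dirs <- list.dirs(dir_path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (!length(dirs)) stop(sprintf("no subject directories under '%s'", dir_path))
  records <- lapply(dirs, read_subject)
  names(records) <- vapply(records, `[[`, "", "subject_id")
  records
}
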