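## Synthetic two-cohort, five-placement, two-protocol wearable data.
##
## The generator emulates the statistical structure the classification study
## design assumes, not biomechanics: postures are placement-specific gravity
## orientations plus Gaussian noise; locomotion adds a harmonic series at a
## per-subject fundamental frequency; GPS tracks move at the drawn speed on
## a constant heading per activity block, with non-level walking adding a
## linear elevation trend (speed x grade). The old cohort's running
## fundamental/speed distributions overlap its walking distributions far
## more than the young cohort's do (older adults run slower, close to their
## walking pace), real-life sessions are noisier than semi-structured ones
## (more so for the young cohort, who roamed freely), the knee placement
## carries the strongest locomotor signal and the pocket placement suffers a
## random per-session orientation (loose pockets). All numeric defaults are
## package constants chosen to satisfy these qualitative contrasts.

#' Activity signal model
#'
#' Parameters of the synthetic signal for one activity within one cohort.
#' Postures have no fundamental frequency; locomotion activities have a
#' per-subject fundamental drawn from `fund_hz`, harmonic amplitudes in g,
#' and a GPS speed distribution; non-level walking additionally has a grade
#' (elevation gain per meter traveled, sign drawn per block).
#'
#' @param activity One of [PATD_ACTIVITIES].
#' @param noise_sd Gaussian per-axis noise sd, g.
#' @param fund_hz `c(mean, sd)` of the fundamental frequency (locomotion) or
#'   `NULL` (postures).
#' @param harmonic_amps Amplitudes (g) of the first three harmonics
#'   (locomotion) or `NULL`.
#' @param speed_mps `c(mean, sd)` of GPS ground speed (0 sd for postures).
#' @param grade `c(mean, sd)` of |elevation gain| per meter (non-level
#'   walking only) or `NULL`.
#' @param sway Mediolateral sway amplitude as a fraction of the first
#'   harmonic's amplitude (locomotion only; slope walking sways slightly
#'   more than level walking).
#' @return A list of class `activity_model`.
#' @export
activity_model <- function(activity, noise_sd, fund_hz = NULL,
                           harmonic_amps = NULL, speed_mps = c(0, 0),
                           grade = NULL, sway = 0.30) {
  activity <- match.arg(activity, PATD_ACTIVITIES)
  if (activity %in% PATD_LOCOMOTION) {
    stopifnot(!is.null(fund_hz), fund_hz[1] > 0, !is.null(harmonic_amps),
              speed_mps[1] >= 0, sway >= 0)
  } else {
    stopifnot(is.null(fund_hz))
  }
  structure(list(activity = activity, noise_sd = noise_sd, fund_hz = fund_hz,
                 harmonic_amps = harmonic_amps, speed_mps = speed_mps,
                 grade = grade, sway = sway),
            class = "activity_model")
}

#' Cohort profile
#'
#' @param cohort `"young"` or `"old"`.
#' @param models Named list mapping each of the six activities to an
#'   [activity_model()].
#' @param real_life_variance_inflation Multiplier applied to noise and
#'   block-level parameter jitter during real-life sessions.
#' @param subject_jitter Named list of between-subject variation magnitudes:
#'   `fund_sd` (Hz), `speed_sd` (m/s), `log_amp_sd`, `log_noise_sd`
#'   (log-normal scale factors), `orient_sd_deg` (per-subject device
#'   orientation jitter, degrees).
#' @return A list of class `cohort_profile`.
#' @export
cohort_profile <- function(cohort, models, real_life_variance_inflation,
                           subject_jitter) {
  cohort <- match.arg(cohort, c("young", "old"))
  stopifnot(setequal(names(models), PATD_ACTIVITIES),
            real_life_variance_inflation >= 1)
  structure(list(cohort = cohort, models = models,
                 real_life_variance_inflation = real_life_variance_inflation,
                 subject_jitter = subject_jitter),
            class = "cohort_profile")
}

#' Default cohort profiles
#'
#' Seed-independent package constants encoding the behavioral contrasts the
#' pipeline is designed to expose: the old cohort runs slower and at a
#' fundamental frequency close to its walking gait, so its running and
#' walking parameter distributions overlap (the young cohort's do not);
#' level and non-level walking have nearly identical accelerometer profiles
#' in both cohorts, so their separation rests on the GPS features; real-life
#' variance inflation is higher for the young cohort (2.0 vs 1.2).
#'
#' @return `list(young = <cohort_profile>, old = <cohort_profile>)`.
#' @export
default_profiles <- function() {
  jitter <- list(fund_sd = 0.08, speed_sd = 0.08, log_amp_sd = 0.10,
                 log_noise_sd = 0.10, orient_sd_deg = 10)
  postures <- function(noise) list(
    lying = activity_model("lying", noise_sd = noise),
    sitting = activity_model("sitting", noise_sd = noise),
    standing = activity_model("standing", noise_sd = noise * 1.3))
  young <- cohort_profile(
    "young",
    c(postures(0.03), list(
      walking = activity_model("walking", noise_sd = 0.05,
                               fund_hz = c(1.90, 0.10),
                               harmonic_amps = c(0.40, 0.18, 0.08),
                               speed_mps = c(1.40, 0.10), sway = 0.30),
      nonlevel_walking = activity_model("nonlevel_walking", noise_sd = 0.05,
                                        fund_hz = c(1.83, 0.10),
                                        harmonic_amps = c(0.38, 0.17, 0.08),
                                        speed_mps = c(1.20, 0.10),
                                        grade = c(0.12, 0.02), sway = 0.30),
      running = activity_model("running", noise_sd = 0.14,
                               fund_hz = c(2.80, 0.15),
                               harmonic_amps = c(0.90, 0.48, 0.23),
                               speed_mps = c(3.00, 0.25), sway = 0.30))),
    real_life_variance_inflation = 2.0, subject_jitter = jitter)
  old <- cohort_profile(
    "old",
    c(postures(0.03), list(
      walking = activity_model("walking", noise_sd = 0.05,
                               fund_hz = c(1.65, 0.10),
                               harmonic_amps = c(0.33, 0.15, 0.07),
                               speed_mps = c(1.10, 0.10), sway = 0.30),
      nonlevel_walking = activity_model("nonlevel_walking", noise_sd = 0.05,
                                        fund_hz = c(1.59, 0.10),
                                        harmonic_amps = c(0.31, 0.14, 0.07),
                                        speed_mps = c(0.95, 0.10),
                                        grade = c(0.12, 0.02), sway = 0.30),
      running = activity_model("running", noise_sd = 0.065,
                               fund_hz = c(1.72, 0.13),
                               harmonic_amps = c(0.34, 0.165, 0.078),
                               speed_mps = c(1.20, 0.20), sway = 0.30))),
    real_life_variance_inflation = 1.2, subject_jitter = jitter)
  list(young = young, old = old)
}

#' Default session schedules
#'
#' Ordered (activity, duration) blocks per protocol. Every activity appears
#' in each protocol; the semi-structured schedule is the scripted sequence
#' all synthetic subjects perform, the real-life schedule a free-form-like
#' mix. Durations are package defaults sized so a full two-session subject
#' stays cheap to featurize.
#'
#' @return Named list of data.tables (`activity`, `duration_s`) keyed by
#'   protocol.
#' @export
default_schedules <- function() {
  list(
    semi_structured = data.table::data.table(
      activity = c("lying", "sitting", "standing", "walking",
                   "nonlevel_walking", "running", "walking", "nonlevel_walking"),
      duration_s = c(30, 30, 30, 60, 60, 40, 30, 30)),
    real_life = data.table::data.table(
      activity = c("sitting", "walking", "standing", "nonlevel_walking",
                   "running", "lying", "walking"),
      duration_s = c(30, 50, 30, 50, 40, 30, 30)))
}

## ---- geometry helpers -------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

## Rodrigues rotation matrix for axis u (unit) and angle theta (radians)
rotation_matrix <- function(u, theta) {
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * ux + (1 - cos(theta)) * (ux %*% ux)
}

random_rotation <- function(max_angle_rad) {
  u <- unit(stats::rnorm(3))
  rotation_matrix(u, stats::runif(1, -max_angle_rad, max_angle_rad))
}

## Device-frame gravity direction per placement and posture. Locomotion uses
## the standing orientation. The tilts are deliberately complementary so no
## single placement resolves every posture pair: the trunk barely tilts
## between sitting and standing (5 deg at the chest, 15 deg at the hips,
## inside the 10 deg per-session orientation jitter) but separates lying
## cleanly, while the thigh-borne placements (pocket, knee) separate
## sitting/standing strongly but rotate into near-sitting angles when lying.
## Fusing placements therefore covers every pair.
placement_orientation <- function(placement, activity) {
  posture <- if (activity %in% PATD_POSTURES) activity else "standing"
  tab <- list(
    chest = list(standing = c(0, 0, 1), sitting = c(0, 0.087, 0.996),
                 lying = c(0.966, 0, 0.259)),
    left_hip = list(standing = c(0, 0, 1), sitting = c(0, 0.259, 0.966),
                    lying = c(1, 0, 0)),
    right_hip = list(standing = c(0, 0, 1), sitting = c(0, -0.259, 0.966),
                     lying = c(-1, 0, 0)),
    left_pocket = list(standing = c(0, 0, 1), sitting = c(0, 0.940, 0.342),
                       lying = c(0, 0.985, 0.174)),
    right_knee = list(standing = c(0, 0, 1), sitting = c(0, 0.866, 0.5),
                      lying = c(0, 0.966, 0.259)))
  unit(tab[[placement]][[posture]])
}

## Locomotor signal amplitude multiplier per placement: the knee sees the
## strongest periodic leg motion, the chest the weakest.
PLACEMENT_AMP <- c(chest = 0.6, left_hip = 0.9, right_hip = 0.9,
                   left_pocket = 1.1, right_knee = 1.6)

## Gait-contrast gain exponent per placement: distal (leg-borne) placements
## amplify the relative amplitude differences between gaits, the trunk
## compresses them. Applied around AMP_REF so the overall scale at the
## reference amplitude is untouched.
PLACEMENT_GAIN_GAMMA <- c(chest = 0.6, left_hip = 0.9, right_hip = 0.9,
                          left_pocket = 1.2, right_knee = 2.0)
AMP_REF <- 0.4

## Local-planar GPS synthesis around a fixed reference; meters east/north
## are converted to degrees on the same 6,371,000 m sphere the haversine
## distance uses, so configured speeds are recoverable to well under 1%.
GPS_REF <- c(lat = 47.37, lon = 8.54)
M_PER_DEG_LAT <- pi * EARTH_RADIUS_M / 180

en_to_latlon <- function(east, north) {
  lat <- GPS_REF["lat"] + north / M_PER_DEG_LAT
  lon <- GPS_REF["lon"] + east / (M_PER_DEG_LAT * cos(GPS_REF["lat"] * pi / 180))
  list(lat = unname(lat), lon = unname(lon))
}

GPS_POS_NOISE_M <- 0.05   # per-fix horizontal noise
GPS_ELEV_NOISE_M <- 0.01  # per-fix elevation noise (idealized, barometric-grade)

## ---- block generation -------------------------------------------------

#' Generate one activity block for one placement
#'
#' Draws the block-level parameters (fundamental, speed, grade sign, phases,
#' heading) from the model, then synthesizes `duration_s` seconds of
#' accelerometer samples and GPS fixes. Postures produce a placement-rotated
#' gravity vector plus noise and a stationary (noisy) GPS track; locomotion
#' adds a three-harmonic series along the gravity axis plus a weaker lateral
#' sway, and a constant-heading GPS track at the drawn speed. Non-level
#' walking adds a linear elevation trend of `speed * grade` m/s with a
#' random sign. Consumes the R random number stream.
#'
#' @param model An [activity_model()].
#' @param placement One of [PATD_POSITIONS].
#' @param duration_s Block duration, seconds (> 0).
#' @param fs_acc,fs_gps Sampling rates, Hz.
#' @param inflation Variance inflation multiplier (>= 1) for noise and
#'   block-level jitter.
#' @param orient Optional 3x3 rotation applied to all direction vectors
#'   (per-subject/session device orientation jitter); identity if `NULL`.
#' @param start List with the track state: `east`, `north`, `elev` (m).
#' @return List with `acc` (data.table `t, ax, ay, az`, `t` starting at 0),
#'   `gps` (data.table `t, lat, lon, elev`), `end` (updated track state) and
#'   `params` (the drawn block parameters).
#' @export
generate_block <- function(model, placement, duration_s, fs_acc = 50,
                           fs_gps = 1, inflation = 1, orient = NULL,
                           start = list(east = 0, north = 0, elev = 400)) {
  stopifnot(duration_s > 0, inflation >= 1)
  if (is.null(orient)) orient <- diag(3)
  t <- seq(0, duration_s - 1 / fs_acc, by = 1 / fs_acc)
  n <- length(t)
  gvec <- as.vector(orient %*% placement_orientation(placement, model$activity))

  is_loco <- model$activity %in% PATD_LOCOMOTION
  if (is_loco) {
    fund <- max(0.2, model$fund_hz[1] + stats::rnorm(1, 0, model$fund_hz[2] * inflation))
    ## gait-contrast gain: distal placements amplify relative amplitude
    ## differences between gaits (exponent around AMP_REF keeps the scale)
    gamma <- PLACEMENT_GAIN_GAMMA[[placement]]
    amp_factor <- if (is.null(model$amp_factor)) 1 else model$amp_factor
    amps <- AMP_REF * (model$harmonic_amps / AMP_REF)^gamma *
      PLACEMENT_AMP[[placement]] * amp_factor *
      exp(stats::rnorm(1, 0, 0.05 * inflation))
    phases <- stats::runif(3, 0, 2 * pi)
    sv <- amps[1] * sin(2 * pi * fund * t + phases[1]) +
      amps[2] * sin(2 * pi * 2 * fund * t + phases[2]) +
      amps[3] * sin(2 * pi * 3 * fund * t + phases[3])
    ref <- if (abs(gvec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit(pracma_cross(gvec, ref))
    sway <- if (is.null(model$sway)) 0.30 else model$sway
    sh <- sway * amps[1] * sin(2 * pi * fund * t + stats::runif(1, 0, 2 * pi))
    base <- outer(sv, gvec) + outer(sh, perp)
    speed <- max(0, model$speed_mps[1] +
                   stats::rnorm(1, 0, model$speed_mps[2] * inflation))
  } else {
    fund <- NA_real_
    base <- matrix(0, n, 3)
    speed <- 0
  }
  ## motion-induced noise scales with the placement's movement amplitude;
  ## resting postures see only the placement-independent sensor noise floor
  noise_sd <- model$noise_sd * inflation *
    (if (is_loco) PLACEMENT_AMP[[placement]] else 1)
  acc <- matrix(gvec, n, 3, byrow = TRUE) + base +
    matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)

  ## GPS track
  tg <- seq(0, duration_s - 1e-9, by = 1 / fs_gps)
  heading <- stats::runif(1, 0, 2 * pi)
  east <- start$east + speed * tg * sin(heading) +
    stats::rnorm(length(tg), 0, GPS_POS_NOISE_M)
  north <- start$north + speed * tg * cos(heading) +
    stats::rnorm(length(tg), 0, GPS_POS_NOISE_M)
  slope <- 0
  if (model$activity == "nonlevel_walking") {
    grade <- max(0.01, model$grade[1] + stats::rnorm(1, 0, model$grade[2] * inflation))
    slope <- sample(c(-1, 1), 1) * grade * speed   # m of elevation per second
  }
  elev <- start$elev + slope * tg + stats::rnorm(length(tg), 0, GPS_ELEV_NOISE_M)
  ll <- en_to_latlon(east, north)

  end <- list(east = start$east + speed * duration_s * sin(heading),
              north = start$north + speed * duration_s * cos(heading),
              elev = start$elev + slope * duration_s)
  list(acc = data.table::data.table(t = t, ax = acc[, 1], ay = acc[, 2],
                                    az = acc[, 3]),
       gps = data.table::data.table(t = tg, lat = ll$lat, lon = ll$lon,
                                    elev = elev),
       end = end,
       params = list(fund_hz = fund, speed_mps = speed, slope = slope,
                     heading = heading))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Per-subject parameter jitter, drawn independently per activity: each
## subject has their own walking, non-level and running gait (fundamental,
## speed, amplitude scale) and noise level, so leave-one-subject-out folds
## face genuinely unseen parameter combinations and cohorts with narrow
## running/walking gaps produce cross-subject confusion.
jitter_profile <- function(profile) {
  j <- profile$subject_jitter
  models <- profile$models
  s_noise <- exp(stats::rnorm(1, 0, j$log_noise_sd))
  for (a in names(models)) {
    m <- models[[a]]
    m$noise_sd <- m$noise_sd * s_noise
    if (!is.null(m$fund_hz)) {
      m$fund_hz[1] <- max(0.2, m$fund_hz[1] + stats::rnorm(1, 0, j$fund_sd))
    }
    if (!is.null(m$harmonic_amps)) {
      ## kept as a separate factor so the placement gait-contrast exponent
      ## amplifies cohort-level gait differences, not subject idiosyncrasy
      m$amp_factor <- exp(stats::rnorm(1, 0, j$log_amp_sd))
    }
    if (m$speed_mps[1] > 0) {
      m$speed_mps[1] <- max(0.1, m$speed_mps[1] + stats::rnorm(1, 0, j$speed_sd))
    }
    models[[a]] <- m
  }
  models
}

#' Generate one synthetic subject
#'
#' Produces both protocol sessions (semi-structured first, then real-life
#' after a 10 s gap) with five placement streams sharing one session clock,
#' a continuous GPS stream, and a label track exactly mirroring the
#' schedules. Consumes the R random number stream.
#'
#' @param subject_id Subject identifier.
#' @param profile A [cohort_profile()].
#' @param schedules As from [default_schedules()].
#' @param fs_acc,fs_gps Sampling rates, Hz.
#' @return A [subject_record()].
#' @export
generate_subject <- function(subject_id, profile, schedules = default_schedules(),
                             fs_acc = 50, fs_gps = 1) {
  models <- jitter_profile(profile)
  orient_sd <- profile$subject_jitter$orient_sd_deg * pi / 180

  acc_parts <- stats::setNames(vector("list", 5L), PATD_POSITIONS)
  for (p in PATD_POSITIONS) acc_parts[[p]] <- list()
  gps_parts <- list()
  lab <- list()
  t_off <- 0
  state <- list(east = 0, north = 0, elev = 400)

  for (proto in PATD_PROTOCOLS) {
    inflation <- if (proto == "real_life") profile$real_life_variance_inflation else 1
    ## per-session, per-placement device orientation jitter; the pocket
    ## additionally gets a rotation uniform within 30 degrees of identity
    orients <- lapply(PATD_POSITIONS, function(p) {
      R <- random_rotation(orient_sd)
      if (p == "left_pocket") R <- random_rotation(30 * pi / 180) %*% R
      R
    })
    names(orients) <- PATD_POSITIONS
    sched <- schedules[[proto]]
    for (b in seq_len(nrow(sched))) {
      act <- sched$activity[b]
      dur <- sched$duration_s[b]
      ## one draw of the block's GPS/gait parameters shared by all placements
      blocks <- list()
      ## draw shared block parameters once by generating the first placement,
      ## then reuse its drawn params for the others via a fixed-param model
      first <- generate_block(models[[act]], PATD_POSITIONS[1], dur,
                              fs_acc, fs_gps, inflation,
                              orient = orients[[PATD_POSITIONS[1]]], start = state)
      blocks[[PATD_POSITIONS[1]]] <- first
      fixed <- models[[act]]
      if (!is.null(fixed$fund_hz)) fixed$fund_hz <- c(first$params$fund_hz, 0)
      fixed$speed_mps <- c(0, 0)  # other placements reuse the first GPS track
      for (p in PATD_POSITIONS[-1]) {
        blk <- generate_block(fixed, p, dur, fs_acc, fs_gps = fs_gps,
                              inflation = inflation, orient = orients[[p]],
                              start = state)
        blocks[[p]] <- blk
      }
      for (p in PATD_POSITIONS) {
        a <- blocks[[p]]$acc
        a[, t := t + t_off]
        acc_parts[[p]][[length(acc_parts[[p]]) + 1L]] <- a
      }
      g <- first$gps
      g[, t := t + t_off]
      gps_parts[[length(gps_parts) + 1L]] <- g
      lab[[length(lab) + 1L]] <- data.table::data.table(
        t_start = t_off, t_end = t_off + dur, activity = act, protocol = proto)
      state <- first$end
      t_off <- t_off + dur
    }
    t_off <- t_off + 10  # inter-session gap, preserved in all streams
  }

  labdt <- data.table::rbindlist(lab)
  acc <- lapply(PATD_POSITIONS, function(p) {
    d <- data.table::rbindlist(acc_parts[[p]])
    acc_stream(subject_id, p, d$t, d$ax, d$ay, d$az)
  })
  names(acc) <- PATD_POSITIONS
  g <- data.table::rbindlist(gps_parts)
  subject_record(subject_id, profile$cohort, acc,
                 label_track(subject_id, labdt$t_start, labdt$t_end,
                             labdt$activity, labdt$protocol),
                 gps_stream(subject_id, g$t, g$lat, g$lon, g$elev))
}

#' Generate a synthetic cohort
#'
#' Deterministic given `seed` (Mersenne-Twister / inversion): the same seed
#' reproduces bit-identical records.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param profile A [cohort_profile()].
#' @param schedules As from [default_schedules()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for subject ids (default the cohort name).
#' @return List of [subject_record()]s.
#' @export
generate_cohort <- function(n_subjects, profile, schedules = default_schedules(),
                            seed = 1L, id_prefix = profile$cohort) {
  stopifnot(n_subjects >= 2L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  lapply(seq_len(n_subjects), function(i) {
    generate_subject(sprintf("%s_%02d", id_prefix, i), profile, schedules)
  })
}

## Overlap coefficient of two +/- 2 sd intervals relative to the narrower
## one; quantifies how much a cohort's running distribution intrudes into
## its walking distribution.
interval_overlap <- function(m1, s1, m2, s2) {
  lo1 <- m1 - 2 * s1; hi1 <- m1 + 2 * s1
  lo2 <- m2 - 2 * s2; hi2 <- m2 + 2 * s2
  inter <- max(0, min(hi1, hi2) - max(lo1, lo2))
  inter / min(hi1 - lo1, hi2 - lo2)
}
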