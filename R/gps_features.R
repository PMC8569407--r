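## Two GPS features per window: average speed and elevation difference.
## Elevation is taken directly from the GPS stream (no map matching or DEM
## correction) and the elevation difference is signed, so uphill and
## downhill segments of non-level walking keep opposite signs.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Coordinate
#' differences are taken in degrees before converting to radians: for the
#' meter-scale steps between consecutive 1 Hz fixes, converting first (as
#' e.g. `geosphere::distHaversine` does) loses the difference's low bits
#' against the ~0.8 rad magnitude of the coordinates themselves, a ~1e-9 m
#' absolute error per segment that is avoidable.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorized).
#' @return Distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  a <- sin((lat2 - lat1) / 2 * to_rad)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin((lon2 - lon1) / 2 * to_rad)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_M * atan2(sqrt(a), sqrt(1 - a))
}

#' GPS features of one window
#'
#' Average speed is the summed consecutive haversine distance divided by the
#' elapsed time between the first and last fix; the elevation difference is
#' the signed last-minus-first elevation. Windows with fewer than two fixes
#' are flagged invalid (`valid = FALSE`) and carry `NA` features; callers
#' decide whether to drop such windows (ACC+GPS tables do, ACC-only tables
#' keep them).
#'
#' @param fixes A data.frame/data.table of time-sorted fixes with columns
#'   `t`, `lat`, `lon`, `elev`, all inside one window.
#' @return A list with `avg_speed` (m/s), `elev_diff` (m), `n_fixes`, `valid`.
#' @export
window_gps_features <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2L) {
    return(list(avg_speed = NA_real_, elev_diff = NA_real_,
                n_fixes = n, valid = FALSE))
  }
  if (any(diff(fixes$t) <= 0)) stop("GPS fixes must be strictly time-ordered")
  d <- haversine_m(fixes$lat[-n], fixes$lon[-n], fixes$lat[-1L], fixes$lon[-1L])
  list(avg_speed = sum(d) / (fixes$t[n] - fixes$t[1L]),
       elev_diff = fixes$elev[n] - fixes$elev[1L],
       n_fixes = n, valid = TRUE)
}
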