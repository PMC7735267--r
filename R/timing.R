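# Migration timing from daily position series: route-fraction thresholds,
# crossing times, duration/speed, equinox and late-winter exclusion rules.

# Equinox dates used by the exclusion rules (month-day, UTC)
.SPRING_EQUINOX <- c(3L, 20L)
.AUTUMN_EQUINOX <- c(9L, 22L)

.equinox_dates <- function(years) {
  c(as.Date(sprintf("%d-%02d-%02d", years, .SPRING_EQUINOX[1], .SPRING_EQUINOX[2])),
    as.Date(sprintf("%d-%02d-%02d", years, .AUTUMN_EQUINOX[1], .AUTUMN_EQUINOX[2])))
}

.days_to_nearest_equinox <- function(dates, which = c("any", "spring")) {
  which <- match.arg(which)
  dates <- as.Date(dates)
  yrs <- as.integer(format(dates, "%Y"))
  vapply(seq_along(dates), function(i) {
    ys <- (yrs[i] - 1):(yrs[i] + 1)
    eq <- if (which == "spring")
      as.Date(sprintf("%d-%02d-%02d", ys, .SPRING_EQUINOX[1], .SPRING_EQUINOX[2]))
    else .equinox_dates(ys)
    min(abs(as.numeric(dates[i] - eq)))
  }, numeric(1))
}

#' Perpendicular threshold lines along a great-circle route
#'
#' Anchors threshold lines at given fractions (defaults 30/50/70%) of the
#' great-circle route from breeding to wintering site; each line runs
#' perpendicular to the route azimuth at its anchor. The three default
#' fractions mark early, middle and late stages of the journey.
#'
#' @param breed_lat,breed_lon,winter_lat,winter_lon route endpoints.
#' @param fractions route fractions strictly between 0 and 1.
#' @return data.frame: `fraction`, `anchor_lat`, `anchor_lon`,
#'   `route_azimuth` (great-circle azimuth at the anchor), `perp_azimuth`.
#' @export
build_thresholds <- function(breed_lat, breed_lon, winter_lat, winter_lon,
                             fractions = c(0.3, 0.5, 0.7)) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must be strictly between 0 and 1", call. = FALSE)
  if (breed_lat == winter_lat && normalize_lon(breed_lon) == normalize_lon(winter_lon))
    stop("identical route endpoints", call. = FALSE)
  fractions <- sort(fractions)
  anchors <- gc_point_at_fraction(breed_lat, breed_lon, winter_lat, winter_lon,
                                  fractions)
  az <- gc_bearing(anchors$lat, anchors$lon, winter_lat, winter_lon)
  data.frame(fraction = fractions, anchor_lat = anchors$lat,
             anchor_lon = anchors$lon, route_azimuth = az,
             perp_azimuth = normalize_bearing(az + 90))
}

#' Signed along-route fraction of points relative to a great-circle route
#'
#' Projects each point onto the breeding-to-wintering great circle and
#' returns its along-route distance as a fraction of the total route length;
#' negative for points behind the start.
#'
#' @param breed_lat,breed_lon,winter_lat,winter_lon route endpoints.
#' @param lat,lon points to project (vectorised).
#' @return numeric vector of signed fractions.
#' @export
route_fraction <- function(breed_lat, breed_lon, winter_lat, winter_lon,
                           lat, lon) {
  total <- great_circle_distance(breed_lat, breed_lon, winter_lat, winter_lon)
  if (total <= 0) stop("identical route endpoints", call. = FALSE)
  along <- as.numeric(geosphere::alongTrackDistance(
    .p(breed_lat, breed_lon), .p(winter_lat, winter_lon), .p(lat, lon),
    r = EARTH_RADIUS_KM))
  # alongTrackDistance is unsigned; a point is behind the start when its
  # bearing from the start differs from the route azimuth by more than 90 deg
  at_start <- great_circle_distance(breed_lat, breed_lon, lat, lon) < 1e-9
  sgn <- rep(1, length(along))
  if (any(!at_start)) {
    b0 <- gc_bearing(breed_lat, breed_lon, winter_lat, winter_lon)
    bp <- rep(NA_real_, length(along))
    bp[!at_start] <- gc_bearing(breed_lat, breed_lon, lat[!at_start], lon[!at_start])
    diffs <- abs(angular_difference(bp, b0))
    behind <- !at_start & !is.na(diffs) & diffs > 90
    sgn[behind] <- -1
  }
  sgn * along / total
}

# Lag-1 autocorrelated standard-normal noise (stationary AR(1))
.ar1_noise <- function(n, ar) {
  e <- numeric(n)
  e[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sqrt(1 - ar^2))
    for (k in 2:n) e[k] <- ar * e[k - 1] + innov[k - 1]
  }
  e
}

# Crossing times (fractional days since 1970-01-01) of a single path over a
# route fraction; linear interpolation between bracketing samples.
.path_crossings <- function(t, frac, line_fraction) {
  keep <- !is.na(frac)
  t <- t[keep]; frac <- frac[keep]
  if (length(t) < 2) return(numeric(0))
  s <- frac - line_fraction
  times <- numeric(0)
  # samples exactly on the line count as crossings at the sample time
  times <- c(times, t[s == 0])
  i <- which(s[-length(s)] * s[-1] < 0)
  if (length(i)) {
    w <- s[i] / (s[i] - s[i + 1])
    times <- c(times, t[i] + w * (t[i + 1] - t[i]))
  }
  sort(times)
}

#' Time a track crosses a route-fraction threshold
#'
#' Computes the signed along-route fraction of every track sample and finds
#' the times at which the track crosses the threshold fraction. A track that
#' never crosses, or crosses more than twice (local wandering near the line),
#' yields `NA` with an explanatory flag — mirroring how threshold-timing
#' calculations fail on real geolocator tracks. When samples carry a
#' positional spread (`spread_km` column), an ensemble of `n_draws` seeded
#' perturbed paths is evaluated and the `quantile` (default 0.50) of the
#' ensemble crossing times returned.
#'
#' @param track data.frame with columns `date` (Date), `lat`, `lon` and
#'   optionally `spread_km` (per-sample position SD in km); dates strictly
#'   increasing, at least 2 samples.
#' @param line_fraction route fraction of the threshold (0-1 exclusive).
#' @param breed_lat,breed_lon,winter_lat,winter_lon route endpoints.
#' @param quantile quantile of crossing times to report (default 0.50).
#' @param n_draws ensemble size when spread is present.
#' @param seed integer seed for the ensemble.
#' @param ensemble_ar lag-1 autocorrelation of the ensemble perturbations
#'   (default 0.9): geolocation error persists across days, so plausible
#'   alternative paths are coherent shifts of the estimated path rather than
#'   independent daily scatter.
#' @return list with `time` (numeric fractional days since 1970-01-01, or
#'   `NA`), `date` (Date, or `NA`) and `flag` (`"ok"`, `"no_transit"`,
#'   `"multi_transit"` or `"ensemble_failed"`).
#' @export
crossing_time <- function(track, line_fraction, breed_lat, breed_lon,
                          winter_lat, winter_lon, quantile = 0.5,
                          n_draws = 200, seed = 1L, ensemble_ar = 0.9) {
  .require_cols(track, c("date", "lat", "lon"), "track")
  if (nrow(track) < 2) stop("track needs at least 2 samples", call. = FALSE)
  t <- as.numeric(as.Date(track$date))
  if (any(diff(t) <= 0)) stop("track dates must be strictly increasing",
                              call. = FALSE)
  one_path <- function(lat, lon) {
    fr <- route_fraction(breed_lat, breed_lon, winter_lat, winter_lon, lat, lon)
    .path_crossings(t, fr, line_fraction)
  }
  finish <- function(time, flag) {
    list(time = time,
         date = if (is.na(time)) as.Date(NA) else as.Date(floor(time),
                                                          origin = "1970-01-01"),
         flag = flag)
  }
  has_spread <- "spread_km" %in% names(track) &&
    any(track$spread_km > 0, na.rm = TRUE)
  if (!has_spread) {
    cr <- one_path(track$lat, track$lon)
    if (length(cr) == 0) return(finish(NA_real_, "no_transit"))
    if (length(cr) > 2) return(finish(NA_real_, "multi_transit"))
    return(finish(stats::quantile(cr, quantile, names = FALSE), "ok"))
  }
  spread <- ifelse(is.na(track$spread_km), 0, track$spread_km)
  sd_lat <- spread / KM_PER_DEG
  sd_lon <- spread / (KM_PER_DEG * cos(.deg2rad(track$lat)))
  set.seed(seed)
  draws <- rep(NA_real_, n_draws)
  nr <- nrow(track)
  for (k in seq_len(n_draws)) {
    cr <- one_path(track$lat + .ar1_noise(nr, ensemble_ar) * sd_lat,
                   track$lon + .ar1_noise(nr, ensemble_ar) * sd_lon)
    if (length(cr) >= 1 && length(cr) <= 2)
      draws[k] <- stats::quantile(cr, 0.5, names = FALSE)
  }
  ok <- !is.na(draws)
  if (mean(ok) < 0.5) return(finish(NA_real_, "ensemble_failed"))
  finish(stats::quantile(draws[ok], quantile, names = FALSE), "ok")
}

#' Migration duration with a one-day floor
#'
#' Days between the early (30%) and late (70%) threshold crossings, floored
#' at one day (sub-day estimates reflect threshold noise, not real transit).
#'
#' @param t30,t70 crossing times (numeric days or Date), `t70 >= t30`.
#' @return duration in fractional days, >= 1.
#' @export
migration_duration <- function(t30, t70) {
  t30 <- as.numeric(t30); t70 <- as.numeric(t70)
  if (any(is.na(t30) | is.na(t70)))
    stop("both crossing times must be non-missing", call. = FALSE)
  if (any(t70 < t30)) stop("t70 earlier than t30", call. = FALSE)
  pmax(1, t70 - t30)
}

#' Migration speed
#' @param distance_km migration distance in km.
#' @param duration_days duration in days (post-floor, >= 1).
#' @return speed in km/day.
#' @export
migration_speed <- function(distance_km, duration_days) {
  if (any(duration_days < 1))
    stop("duration must be >= 1 day (apply migration_duration first)",
         call. = FALSE)
  distance_km / duration_days
}

#' Equinox exclusion rule for timing estimates
#'
#' Timing estimates of near-north-south movements are unreliable close to an
#' equinox (latitude is poorly resolved). An estimate is dropped iff its date
#' lies within `window_days` of an equinox (Mar 20 / Sep 22) and the route
#' bearing is within `ns_tolerance_deg` of due north or due south.
#'
#' @param dates movement dates (Date, vectorised).
#' @param route_bearing route bearing(s) in degrees.
#' @param window_days days around the equinox (default 7).
#' @param ns_tolerance_deg angular tolerance around 0/180 (default 15).
#' @return logical vector: `TRUE` = keep, `FALSE` = drop.
#' @export
equinox_filter <- function(dates, route_bearing, window_days = 7,
                           ns_tolerance_deg = 15) {
  n <- max(length(dates), length(route_bearing))
  dates <- rep_len(as.Date(dates), n)
  route_bearing <- rep_len(normalize_bearing(route_bearing), n)
  near_eq <- .days_to_nearest_equinox(dates) <= window_days
  ns_dist <- pmin(abs(angular_difference(route_bearing, 0)),
                  abs(angular_difference(route_bearing, 180)))
  !(near_eq & ns_dist <= ns_tolerance_deg)
}

#' Truncate unreliable late-winter positions
#'
#' If a tag stopped operating within `window_days` (default 21, either side)
#' of the spring equinox, position estimates after 1 January of that winter
#' are dropped: tracks ending near the equinox carry unreliable late-winter
#' latitudes. Idempotent; sets attribute `truncated` on the result.
#'
#' @param track data.frame with a `date` column (Date).
#' @param last_fix_date date of the tag's final fix (default: last track date).
#' @param window_days half-width of the window around the spring equinox.
#' @return the track, possibly with post-1-January rows removed; attribute
#'   `truncated` is `TRUE` when rows were dropped (or the rule applied).
#' @export
truncate_late_winter <- function(track, last_fix_date = max(track$date),
                                 window_days = 21) {
  .require_cols(track, "date", "track")
  last_fix_date <- as.Date(last_fix_date)
  if (.days_to_nearest_equinox(last_fix_date, "spring") > window_days) {
    attr(track, "truncated") <- FALSE
    return(track)
  }
  yr <- as.integer(format(last_fix_date, "%Y"))
  eq <- as.Date(sprintf("%d-%02d-%02d", c(yr, yr + 1),
                        .SPRING_EQUINOX[1], .SPRING_EQUINOX[2]))
  eq <- eq[which.min(abs(as.numeric(last_fix_date - eq)))]
  cutoff <- as.Date(sprintf("%d-01-01", as.integer(format(eq, "%Y"))))
  out <- track[as.Date(track$date) <= cutoff, , drop = FALSE]
  attr(out, "truncated") <- TRUE
  out
}

#' Keep one randomly chosen track per bird
#'
#' Repeat tracks of the same individual are not independent; for the timing
#' models exactly one track per bird is retained, chosen uniformly at random
#' under the given seed.
#'
#' @param records data.frame with a bird-identity column.
#' @param id_col name of the identity column (default `"bird_id"`).
#' @param seed integer seed.
#' @return subset of `records` with one row per bird.
#' @export
dedupe_repeat_tracks <- function(records, id_col = "bird_id", seed = 1L) {
  .require_cols(records, id_col, "record table")
  set.seed(seed)
  pick <- unlist(lapply(split(seq_len(nrow(records)), records[[id_col]]),
                        function(idx) idx[sample.int(length(idx), 1)]),
                 use.names = FALSE)
  out <- records[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Timing records for a cohort of tracks
#'
#' For each bird, builds the 30/50/70% threshold lines from its breeding and
#' wintering sites, estimates the three crossing times, applies the equinox
#' exclusion rule to each estimate, and derives duration (30% to 70%, floored
#' at one day) and speed (great-circle distance / duration).
#'
#' @param tracks data.frame of samples: `bird_id`, `date`, `lat`, `lon`,
#'   optional `spread_km`.
#' @param birds data.frame: `bird_id`, `breed_lat`, `breed_lon`,
#'   `winter_lat`, `winter_lon`.
#' @param fractions threshold fractions (default 0.3, 0.5, 0.7).
#' @param seed seed for ensemble crossing times.
#' @param ... passed to [crossing_time()].
#' @return data.frame, one row per bird: crossing times `t30`, `t50`, `t70`
#'   (fractional days since 1970-01-01, `NA` when failed or excluded),
#'   `duration_days`, `speed_km_per_day`, `distance_km`, and a
#'   semicolon-separated `flags` column.
#' @export
timing_records <- function(tracks, birds, fractions = c(0.3, 0.5, 0.7),
                           seed = 1L, ...) {
  .require_cols(tracks, c("bird_id", "date", "lat", "lon"), "track table")
  .require_cols(birds, c("bird_id", "breed_lat", "breed_lon",
                         "winter_lat", "winter_lon"), "bird table")
  fractions <- sort(fractions)
  out <- lapply(seq_len(nrow(birds)), function(i) {
    b <- birds[i, ]
    tr <- tracks[tracks$bird_id == b$bird_id, , drop = FALSE]
    tr <- tr[order(tr$date), , drop = FALSE]
    flags <- character(0)
    times <- rep(NA_real_, length(fractions))
    if (nrow(tr) >= 2) {
      bearing <- rhumb_bearing(b$breed_lat, b$breed_lon,
                               b$winter_lat, b$winter_lon)
      for (k in seq_along(fractions)) {
        ct <- crossing_time(tr, fractions[k], b$breed_lat, b$breed_lon,
                            b$winter_lat, b$winter_lon, seed = seed, ...)
        if (!is.na(ct$time) &&
            !equinox_filter(ct$date, bearing)) {
          flags <- c(flags, sprintf("t%02.0f_equinox_excluded",
                                    100 * fractions[k]))
        } else if (is.na(ct$time)) {
          flags <- c(flags, sprintf("t%02.0f_%s", 100 * fractions[k], ct$flag))
        } else {
          times[k] <- ct$time
        }
      }
    } else flags <- "track_too_short"
    dist <- great_circle_distance(b$breed_lat, b$breed_lon,
                                  b$winter_lat, b$winter_lon)
    dur <- if (!is.na(times[1]) && !is.na(times[length(times)]) &&
               times[length(times)] >= times[1])
      migration_duration(times[1], times[length(times)]) else NA_real_
    data.frame(bird_id = b$bird_id,
               t30 = times[1],
               t50 = if (length(fractions) > 2) times[2] else NA_real_,
               t70 = times[length(times)],
               duration_days = dur,
               distance_km = dist,
               speed_km_per_day = if (is.na(dur)) NA_real_ else
                 migration_speed(dist, dur),
               flags = paste(flags, collapse = ";"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
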