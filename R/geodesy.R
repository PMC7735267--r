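# Geodesic and circular-statistics primitives shared by every analysis stage.
# All coordinates are decimal degrees WGS84 (spherical Earth), distances km,
# bearings degrees clockwise from true north in [0, 360).

#' Mean Earth radius (km) of the spherical model used throughout
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Kilometres per degree of arc on the spherical Earth model
#' @export
KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Normalize longitudes to (-180, 180]
#' @param lon numeric vector of longitudes in degrees.
#' @return longitudes wrapped into (-180, 180].
#' @export
normalize_lon <- function(lon) {
  out <- (lon + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

#' Normalize bearings to [0, 360)
#' @param bearing numeric vector of bearings in degrees.
#' @return bearings wrapped into [0, 360).
#' @export
normalize_bearing <- function(bearing) bearing %% 360

.check_latlon <- function(lat, lon, what = "point") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinate in ", what, call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of [-90, 90] in ", what, call. = FALSE)
  invisible(NULL)
}

# geosphere wants lon-lat matrices
.p <- function(lat, lon) cbind(normalize_lon(lon), lat)

#' Rhumb-line (loxodrome) bearing between two points
#'
#' Constant-compass bearing from an origin to a destination, the convention
#' used to summarise a bird's autumn migration direction from its breeding
#' and wintering sites. Longitude differences are taken on the shortest arc,
#' so routes near the antimeridian are handled.
#'
#' @param lat1,lon1 origin coordinates, decimal degrees.
#' @param lat2,lon2 destination coordinates, decimal degrees.
#' @return bearing(s) in degrees clockwise from north, in [0, 360).
#'   Identical origin and destination is an error (direction undefined).
#' @examples
#' rhumb_bearing(48, 14, 38, 14) # due south, 180
#' @export
rhumb_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1, "origin")
  .check_latlon(lat2, lon2, "destination")
  # difference longitudes on the shortest arc before handing to geosphere,
  # whose rhumb bearing otherwise runs the long way round
  lon1 <- normalize_lon(lon1)
  lon2 <- lon1 + angular_difference(normalize_lon(lon2), lon1)
  b <- suppressWarnings(
    geosphere::bearingRhumb(cbind(lon1, lat1), cbind(lon2, lat2)))
  if (any(is.na(b)))
    stop("rhumb bearing undefined: origin and destination coincide",
         call. = FALSE)
  normalize_bearing(as.numeric(b))
}

#' Rhumb-line destination point
#'
#' Point reached by travelling a given distance along a constant bearing.
#' Inverse of [rhumb_bearing()]: for positive distances,
#' `rhumb_bearing(origin, destination)` recovers the bearing.
#'
#' @param lat,lon origin coordinates, decimal degrees.
#' @param bearing degrees clockwise from north.
#' @param distance_km distance in km (>= 0).
#' @return data.frame with columns `lat`, `lon`.
#' @export
rhumb_destination <- function(lat, lon, bearing, distance_km) {
  .check_latlon(lat, lon, "origin")
  if (any(distance_km < 0)) stop("distance must be >= 0", call. = FALSE)
  bearing <- normalize_bearing(bearing)
  # a rhumb line changes latitude at cos(bearing) * distance; refuse paths
  # that would run off the sphere over a pole
  dlat <- .rad2deg(distance_km / EARTH_RADIUS_KM) * cos(.deg2rad(bearing))
  if (any(abs(lat + dlat) > 90 + 1e-9))
    stop("rhumb destination crosses a pole: latitude out of range",
         call. = FALSE)
  d <- suppressWarnings(
    geosphere::destPointRhumb(.p(lat, lon), bearing, distance_km * 1000,
                              r = EARTH_RADIUS_KM * 1000))
  out_lat <- d[, 2]
  if (any(abs(out_lat) > 90 | is.na(out_lat)))
    stop("rhumb destination crosses a pole: latitude out of range",
         call. = FALSE)
  data.frame(lat = unname(out_lat), lon = unname(normalize_lon(d[, 1])))
}

#' Great-circle (haversine) distance in km
#'
#' Shortest distance on the sphere, used for migration distances and as the
#' reference axis for migration-progress thresholds.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @examples
#' great_circle_distance(0, 0, 0, 1) # ~111.195 km
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1, "a")
  .check_latlon(lat2, lon2, "b")
  as.numeric(geosphere::distHaversine(.p(lat1, lon1), .p(lat2, lon2),
                                      r = EARTH_RADIUS_KM))
}

#' Point at a fraction of the way along a great-circle route
#'
#' Spherical linear interpolation between two points; fraction 0 is the
#' start, 1 the end. Antipodal endpoints have no unique route and error.
#'
#' @param lat1,lon1,lat2,lon2 route endpoints, decimal degrees.
#' @param fraction numeric vector of fractions in [0, 1].
#' @return data.frame with columns `lat`, `lon`, one row per fraction.
#' @export
gc_point_at_fraction <- function(lat1, lon1, lat2, lon2, fraction) {
  .check_latlon(lat1, lon1, "start")
  .check_latlon(lat2, lon2, "end")
  if (any(fraction < 0 | fraction > 1))
    stop("fraction must be in [0, 1]", call. = FALSE)
  phi1 <- .deg2rad(lat1); la1 <- .deg2rad(normalize_lon(lon1))
  phi2 <- .deg2rad(lat2); la2 <- .deg2rad(normalize_lon(lon2))
  a <- c(cos(phi1) * cos(la1), cos(phi1) * sin(la1), sin(phi1))
  b <- c(cos(phi2) * cos(la2), cos(phi2) * sin(la2), sin(phi2))
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) {
    return(data.frame(lat = rep(lat1, length(fraction)),
                      lon = rep(normalize_lon(lon1), length(fraction))))
  }
  if (abs(pi - omega) < 1e-9)
    stop("antipodal endpoints: great-circle route not unique", call. = FALSE)
  out <- t(vapply(fraction, function(f) {
    v <- (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
    c(.rad2deg(asin(max(-1, min(1, v[3])))), .rad2deg(atan2(v[2], v[1])))
  }, numeric(2)))
  data.frame(lat = out[, 1], lon = normalize_lon(out[, 2]))
}

#' Initial great-circle bearing between two points
#' @inheritParams great_circle_distance
#' @return bearing in degrees, [0, 360).
#' @export
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  normalize_bearing(as.numeric(
    geosphere::bearing(.p(lat1, lon1), .p(lat2, lon2))))
}

#' Signed smallest angular difference a - b
#'
#' @param a,b angles in degrees.
#' @return signed difference in (-180, 180].
#' @export
angular_difference <- function(a, b) {
  d <- (a - b) %% 360
  d - 360 * (!is.na(d) & d > 180)
}

#' Circular mean of directions
#' @param directions bearings in degrees.
#' @return mean direction in [0, 360).
#' @export
circular_mean <- function(directions) {
  if (length(directions) < 1) stop("need at least one direction", call. = FALSE)
  r <- .deg2rad(directions)
  normalize_bearing(.rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Circular variance of directions
#'
#' One minus the mean resultant length: 0 for perfectly concentrated
#' directions, 1 for complete angular cancellation.
#'
#' @param directions bearings in degrees (at least one).
#' @return variance in [0, 1].
#' @export
circular_variance <- function(directions) {
  if (length(directions) < 1) stop("need at least one direction", call. = FALSE)
  r <- .deg2rad(directions)
  1 - sqrt(mean(cos(r))^2 + mean(sin(r))^2)
}

#' Fisher-Lee circular correlation coefficient
#'
#' Correlation between two samples of angles,
#' sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) normalised by the root product of
#' the two sums of squared sines. Equals 1 when `b == a` and -1 when
#' `b == -a` (for non-constant `a`).
#'
#' @param a,b equal-length vectors of angles in degrees (length >= 3).
#' @return coefficient in [-1, 1]. An angularly constant sample (zero
#'   denominator) is an error, not a silent zero.
#' @export
circular_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 paired angles", call. = FALSE)
  ar <- .deg2rad(a); br <- .deg2rad(b)
  ij <- utils::combn(n, 2)
  sa <- sin(ar[ij[1, ]] - ar[ij[2, ]])
  sb <- sin(br[ij[1, ]] - br[ij[2, ]])
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12)
    stop("circular correlation undefined: angularly constant sample",
         call. = FALSE)
  sum(sa * sb) / den
}
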