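# Seeded synthetic-data generators emulating the statistical structure of a
# geolocator migratory-divide study: breeding sites on an east-west transect,
# autumn directions from a sigmoid cline plus Gaussian noise, daily tracks
# with inflated latitude noise near equinoxes, per-phenotype arrival dates,
# and stratified ringing-recovery records.

#' Synthetic-study configuration
#'
#' Defaults are calibrated to the divide study's reported quantities: cline
#' centre 14.0 deg E and width 0.36 deg longitude (about 27 km at 47.6 deg N)
#' with asymptotic directions 245/150 deg and individual direction SD 20 deg;
#' spring arrival of intermediate (S) birds 8.9 d earlier than SW/SE and of
#' NW birds 9.8 d earlier than SW; S spring migration start 14.6 d earlier
#' (SD 7 d). Track noise uses the geolocation error structure: longitude SD
#' 0.5 deg, latitude SD 1.5 deg, latitude noise tripled within 7 days of an
#' equinox.
#'
#' @param cline a [cline_params()] for the direction cline.
#' @param transect_lat latitude range of breeding sites (deg N).
#' @param lon_range longitude range of breeding sites (deg E).
#' @param divide_bounds longitudes bounding the divide zone, for zone labels.
#' @param distance_km per-phenotype migration distance mean/SD (km).
#' @param arrival per-phenotype spring-arrival models (day of year).
#' @param spring_start per-phenotype spring-migration-start models.
#' @param track list of track-generation settings: `lon_sd`, `lat_sd`,
#'   `equinox_factor`, `equinox_window` (days), `speed_mean`, `speed_sd`,
#'   `speed_min` (km/day), `depart_doy_mean`, `depart_doy_sd`, `pre_days`,
#'   `post_days`, `noise_ar` (lag-1 autocorrelation of the position noise).
#' @param year calendar year of the simulated autumn migration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(cline = cline_params(14.0, 0.36, 245, 150, 20),
                       transect_lat = c(46.6, 48.7),
                       lon_range = c(12, 16),
                       divide_bounds = c(13.5, 14.5),
                       distance_km = list(SW = c(mean = 1800, sd = 250),
                                          S = c(mean = 1300, sd = 250),
                                          SE = c(mean = 1900, sd = 250),
                                          NW = c(mean = 1100, sd = 200)),
                       arrival = list(SW = arrival_gaussian(100, 6),
                                      SE = arrival_gaussian(100, 6),
                                      S = arrival_gaussian(91.1, 6),
                                      NW = arrival_gaussian(90.2, 6)),
                       spring_start = list(SW = arrival_gaussian(75, 7),
                                           SE = arrival_gaussian(75, 7),
                                           S = arrival_gaussian(60.4, 7),
                                           NW = arrival_gaussian(70, 7)),
                       track = list(lon_sd = 0.5, lat_sd = 1.5,
                                    equinox_factor = 3, equinox_window = 7,
                                    speed_mean = 150, speed_sd = 30,
                                    speed_min = 60,
                                    depart_doy_mean = 255, depart_doy_sd = 5,
                                    pre_days = 10, post_days = 15,
                                    noise_ar = 0.6),
                       year = 2015) {
  stopifnot(inherits(cline, "cline_params"),
            track$lon_sd >= 0, track$lat_sd >= 0, track$equinox_factor >= 1)
  structure(list(cline = cline, transect_lat = transect_lat,
                 lon_range = lon_range, divide_bounds = divide_bounds,
                 distance_km = distance_km, arrival = arrival,
                 spring_start = spring_start, track = track, year = year),
            class = "sim_config")
}

# provisional phenotype from the autumn direction alone, used to pick a
# distance model before the wintering site exists
.direction_class <- function(direction) {
  ifelse(direction >= 215, "SW", ifelse(direction <= 180, "SE", "S"))
}

#' Generate a synthetic divide cohort
#'
#' Breeding longitudes are drawn along the transect (half uniform over
#' `lon_range`, half concentrated near the cline centre, emulating dense
#' sampling of the divide), breeding latitudes uniform over `transect_lat`.
#' Each bird's autumn direction is the cline mean at its longitude plus
#' Normal(0, sigma) noise; a migration distance is drawn from the
#' phenotype-specific model and the wintering site placed by rhumb-line
#' projection, then classified with [classify_winter()].
#'
#' @param n number of birds.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param lons optional vector of breeding longitudes (length `n`), replacing
#'   the default sampling scheme.
#' @return data.frame: `bird_id`, `year`, `sex`, `region`, `zone`
#'   (west/divide/east of the divide), breeding and wintering coordinates,
#'   `true_direction` (pre-noise cline mean), `direction_deg`, `distance_km`,
#'   `phenotype`.
#' @export
generate_divide_cohort <- function(n, cfg = sim_config(), seed = 1L,
                                   lons = NULL) {
  set.seed(seed)
  if (is.null(lons)) {
    n_unif <- ceiling(n / 2)
    lons <- c(stats::runif(n_unif, cfg$lon_range[1], cfg$lon_range[2]),
              pmin(pmax(stats::rnorm(n - n_unif, cfg$cline$center, 0.5),
                        cfg$lon_range[1]), cfg$lon_range[2]))
  }
  stopifnot(length(lons) == n)
  lats <- stats::runif(n, cfg$transect_lat[1], cfg$transect_lat[2])
  mu <- cline_mean(lons, cfg$cline)
  direction <- mu + stats::rnorm(n, 0, cfg$cline$sigma)
  cls <- .direction_class(direction)
  dist <- vapply(cls, function(k) {
    m <- cfg$distance_km[[k]]
    max(600, stats::rnorm(1, m[["mean"]], m[["sd"]]))
  }, numeric(1))
  wint <- rhumb_destination(lats, lons, normalize_bearing(direction), dist)
  zone <- ifelse(lons < cfg$divide_bounds[1], "west",
                 ifelse(lons > cfg$divide_bounds[2], "east", "divide"))
  data.frame(bird_id = sprintf("bird%03d", seq_len(n)),
             year = cfg$year, sex = "M", region = "divide", zone = zone,
             breed_lat = lats, breed_lon = lons,
             winter_lat = wint$lat, winter_lon = wint$lon,
             true_direction = mu, direction_deg = normalize_bearing(direction),
             distance_km = dist,
             phenotype = classify_winter(wint$lat, wint$lon))
}

#' Generate daily geolocator-like tracks for a cohort
#'
#' Each bird departs around the configured autumn date, travels along the
#' breeding-to-wintering great circle at a constant drawn speed, and is
#' stationary before departure and after arrival. Gaussian position noise
#' (lag-1 autocorrelated, emulating the persistence of geolocation error) is
#' added per day, with latitude noise inflated by `equinox_factor` within
#' `equinox_window` days of an equinox. True threshold-crossing dates are
#' returned alongside as ground truth.
#'
#' @param cohort data.frame from [generate_divide_cohort()] (needs
#'   coordinates and `bird_id`).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param fractions route fractions whose true crossing dates are recorded.
#' @param noise overall noise multiplier (0 gives noiseless tracks).
#' @return list with `tracks` (bird_id, season, date, lat, lon, spread_km)
#'   and `truth` (bird_id, depart, arrive, speed_km_per_day, distance_km and
#'   one `t<frac>` column of true crossing times — numeric days since
#'   1970-01-01 — per fraction).
#' @export
generate_tracks <- function(cohort, cfg = sim_config(), seed = 1L,
                            fractions = c(0.3, 0.5, 0.7), noise = 1) {
  set.seed(seed)
  tr <- cfg$track
  all_tracks <- vector("list", nrow(cohort))
  all_truth <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    b <- cohort[i, ]
    speed <- max(tr$speed_min, stats::rnorm(1, tr$speed_mean, tr$speed_sd))
    depart <- as.Date(sprintf("%d-01-01", cfg$year)) - 1 +
      round(stats::rnorm(1, tr$depart_doy_mean, tr$depart_doy_sd))
    dist <- great_circle_distance(b$breed_lat, b$breed_lon,
                                  b$winter_lat, b$winter_lon)
    travel_days <- dist / speed
    dates <- seq(depart - tr$pre_days,
                 depart + ceiling(travel_days) + tr$post_days, by = "day")
    f <- pmin(pmax(as.numeric(dates - depart) / travel_days, 0), 1)
    pos <- gc_point_at_fraction(b$breed_lat, b$breed_lon,
                                b$winter_lat, b$winter_lon, f)
    nd <- length(dates)
    eq_near <- .days_to_nearest_equinox(dates) <= tr$equinox_window
    lat_sd <- noise * tr$lat_sd * ifelse(eq_near, tr$equinox_factor, 1)
    lon_sd <- noise * tr$lon_sd
    ar <- tr$noise_ar
    lat_obs <- pos$lat + .ar1_noise(nd, ar) * lat_sd
    lon_obs <- pos$lon + .ar1_noise(nd, ar) * lon_sd
    all_tracks[[i]] <- data.frame(bird_id = b$bird_id, season = "autumn",
                                  date = dates,
                                  lat = pmin(pmax(lat_obs, -90), 90),
                                  lon = normalize_lon(lon_obs),
                                  spread_km = lat_sd * KM_PER_DEG)
    tt <- as.numeric(depart) + fractions * travel_days
    truth <- data.frame(bird_id = b$bird_id, depart = depart,
                        arrive = depart + travel_days,
                        speed_km_per_day = speed, distance_km = dist)
    truth[sprintf("t%02.0f", 100 * fractions)] <- as.list(tt)
    all_truth[[i]] <- truth
  }
  list(tracks = do.call(rbind, all_tracks),
       truth = do.call(rbind, all_truth))
}

#' Generate per-bird arrival and spring-start dates
#'
#' Draws each bird's spring arrival day and spring migration start day from
#' its phenotype's configured model; the generating between-phenotype shifts
#' are recorded as ground truth in the `shifts` attribute.
#'
#' @param cohort data.frame with `bird_id` and `phenotype`.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return data.frame: `bird_id`, `phenotype`, `arrival_doy`,
#'   `spring_start_doy`; attribute `shifts` holds the generating model means.
#' @export
generate_arrivals <- function(cohort, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ph <- as.character(cohort$phenotype)
  unknown <- setdiff(unique(ph), names(cfg$arrival))
  if (length(unknown))
    stop("no arrival model for phenotype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  draw <- function(models) {
    out <- numeric(nrow(cohort))
    for (p in unique(ph))
      out[ph == p] <- .draw_arrivals(models[[p]], sum(ph == p))
    out
  }
  out <- data.frame(bird_id = cohort$bird_id, phenotype = cohort$phenotype,
                    arrival_doy = draw(cfg$arrival),
                    spring_start_doy = draw(cfg$spring_start))
  attr(out, "shifts") <- list(
    arrival = vapply(cfg$arrival, `[[`, numeric(1), "mean"),
    spring_start = vapply(cfg$spring_start, `[[`, numeric(1), "mean"))
  out
}

#' Generate stratified ringing-recovery records
#'
#' Produces a deterministic stratum of seven records — one passing every
#' filter criterion and one failing each single criterion (breeding box,
#' breeding window, recovery window, bearing, distance) plus one passing
#' record for a ring with two re-encounters — with the expected verdict and
#' failed criterion stored per record, and optionally `n_random` additional
#' seeded random records around the breeding region.
#'
#' @param cfg a [sim_config()] (used for the year only).
#' @param seed integer seed for the random stratum.
#' @param n_random number of additional random records.
#' @return data.frame: `ring_id`, `date1`, `lat1`, `lon1`, `date2`, `lat2`,
#'   `lon2`, `expected_pass`, `expected_reason`.
#' @export
generate_recoveries <- function(cfg = sim_config(), seed = 1L, n_random = 0) {
  y <- cfg$year
  d <- function(md, yy = y) as.Date(sprintf("%d-%s", yy, md))
  base <- data.frame(
    ring_id = sprintf("ring%02d", 1:7),
    date1 = d(rep("06-10", 7)),
    lat1 = c(47.5, 45.0, 47.5, 47.5, 47.5, 47.5, 47.2),
    lon1 = c(14, 14, 14, 14, 14, 14, 15),
    date2 = c(d("12-01"), d("12-01"), d("12-01"), d("07-01"), d("12-01"),
              d("12-01"), d("11-15")),
    lat2 = c(42.5, 38.0, 42.5, 42.5, 52.5, 45.0, 40.0),
    lon2 = c(14, 14, 14, 14, 14, 14, 16),
    expected_pass = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    expected_reason = c("", "breeding_box", "breeding_window",
                        "recovery_window", "bearing", "distance", ""))
  base$date1[3] <- d("09-01")
  # ring07 gets a second, failing re-encounter (multi-encounter ring)
  extra <- base[7, ]
  extra$date2 <- d("07-20"); extra$lat2 <- 46.9; extra$lon2 <- 15.2
  extra$expected_pass <- FALSE
  extra$expected_reason <- "recovery_window;distance"
  out <- rbind(base, extra)
  if (n_random > 0) {
    set.seed(seed)
    rl <- data.frame(
      ring_id = sprintf("rnd%03d", seq_len(n_random)),
      date1 = d("01-01") + sample(120:240, n_random, replace = TRUE),
      lat1 = stats::runif(n_random, 45.5, 49.5),
      lon1 = stats::runif(n_random, 7, 21),
      lat2 = stats::runif(n_random, 35, 50),
      lon2 = stats::runif(n_random, -5, 25))
    rl$date2 <- rl$date1 + sample(60:300, n_random, replace = TRUE)
    ev <- .evaluate_recoveries(rl, filter_criteria())
    rl$expected_pass <- ev$pass
    rl$expected_reason <- ev$reasons
    out <- rbind(out, rl[names(out)])
  }
  rownames(out) <- NULL
  out
}
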