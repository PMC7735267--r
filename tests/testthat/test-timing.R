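test_that("threshold lines sit at the right anchors with perpendicular azimuths", {
  th <- build_thresholds(0, 0, 0, 10, c(0.5))
  expect_equal(th$anchor_lat, 0, tolerance = 1e-9)
  expect_equal(th$anchor_lon, 5, tolerance = 1e-9)
  expect_equal(th$route_azimuth, 90, tolerance = 1e-6)
  expect_equal(th$perp_azimuth %% 180, 0, tolerance = 1e-6)
  # meridian route: anchor latitude linear in fraction
  th2 <- build_thresholds(50, 14, 40, 14, c(0.3, 0.5, 0.7))
  expect_equal(th2$anchor_lat, 50 - c(3, 5, 7), tolerance = 1e-9)
  expect_true(all(diff(th2$anchor_lat) < 0)) # ordered along the route
  expect_error(build_thresholds(1, 1, 1, 1), "identical")
  expect_error(build_thresholds(0, 0, 0, 10, c(0, 0.5)), "strictly between")
})

test_that("signed route fractions project points onto the route", {
  f <- route_fraction(0, 0, 0, 10, c(0, 0, 0, 1), c(0, 5, 10, -2))
  expect_equal(f[1:3], c(0, 0.5, 1), tolerance = 1e-6)
  expect_lt(f[4], 0) # behind the start
})

test_that("crossing time interpolates linearly and flags failures", {
  tr <- equator_track()
  t0 <- as.numeric(tr$date[1])
  ct <- crossing_time(tr, 0.3, 0, 0, 0, 10)
  expect_equal(ct$flag, "ok")
  expect_equal(ct$time, t0 + 3, tolerance = 1e-6)
  # time-translation equivariance
  tr2 <- tr; tr2$date <- tr2$date + 37
  ct2 <- crossing_time(tr2, 0.3, 0, 0, 0, 10)
  expect_equal(ct2$time - ct$time, 37, tolerance = 1e-9)
  # stationary track never transits
  st <- data.frame(date = tr$date, lat = 0, lon = 0)
  expect_equal(crossing_time(st, 0.3, 0, 0, 0, 10)$flag, "no_transit")
  # wandering track crosses more than twice -> failed estimate
  wob <- data.frame(date = tr$date, lat = 0,
                    lon = c(0, 4, 2, 5, 2, 5, 2, 6, 8, 9, 10))
  expect_equal(crossing_time(wob, 0.3, 0, 0, 0, 10)$flag, "multi_transit")
})

test_that("ordered thresholds give ordered crossing times on monotone tracks", {
  tr <- equator_track()
  times <- vapply(c(0.3, 0.5, 0.7), function(f)
    crossing_time(tr, f, 0, 0, 0, 10)$time, numeric(1))
  expect_true(all(diff(times) > 0))
})

test_that("ensemble crossing with known truth is accurate and seeded", {
  set.seed(77)
  tr <- equator_track()
  tr$lon <- tr$lon + rnorm(11, 0, 0.2)
  tr$spread_km <- 30
  a <- crossing_time(tr, 0.5, 0, 0, 0, 10, n_draws = 100, seed = 5)
  b <- crossing_time(tr, 0.5, 0, 0, 0, 10, n_draws = 100, seed = 5)
  expect_identical(a, b)
  expect_equal(a$flag, "ok")
  expect_lt(abs(a$time - (as.numeric(tr$date[1]) + 5)), 1)
})

test_that("duration floors at one day and speed divides distance by duration", {
  expect_equal(migration_duration(10, 10.4), 1)
  expect_equal(migration_duration(10, 15.2), 5.2)
  expect_equal(migration_duration(10, 11), 1)
  expect_error(migration_duration(12, 10), "earlier")
  expect_equal(migration_speed(1000, 5), 200)
  expect_equal(migration_speed(940, 1), 940)
  expect_error(migration_speed(500, 0.4), ">= 1")
})

test_that("the equinox rule drops only near-equinox near-meridional movements", {
  expect_false(equinox_filter(as.Date("2015-09-25"), 170))
  expect_true(equinox_filter(as.Date("2015-09-25"), 120))
  expect_true(equinox_filter(as.Date("2015-07-01"), 180))
  expect_false(equinox_filter(as.Date("2016-03-18"), 355))
  # idempotent by construction: pure predicate of (date, bearing)
  d <- as.Date("2015-09-20") + 0:10
  expect_identical(equinox_filter(d, 175), equinox_filter(d, 175))
})

test_that("late-winter truncation applies exactly within the equinox window", {
  tr <- data.frame(date = seq(as.Date("2014-11-01"), as.Date("2015-03-10"),
                              by = "day"), lat = 40, lon = 5)
  out <- truncate_late_winter(tr)
  expect_true(attr(out, "truncated"))
  expect_lte(max(out$date), as.Date("2015-01-01"))
  # stopping 47 days before the equinox: unchanged
  tr2 <- tr[tr$date <= as.Date("2015-02-01"), ]
  out2 <- truncate_late_winter(tr2)
  expect_false(attr(out2, "truncated"))
  expect_equal(nrow(out2), nrow(tr2))
  # stopping well after the equinox + window: unchanged
  tr3 <- data.frame(date = seq(as.Date("2015-01-05"), as.Date("2015-04-15"),
                               by = "day"), lat = 40, lon = 5)
  expect_false(attr(truncate_late_winter(tr3), "truncated"))
  # idempotent
  expect_equal(nrow(truncate_late_winter(out)), nrow(out))
})

test_that("dedupe keeps exactly one seeded-reproducible track per bird", {
  rec <- data.frame(bird_id = c("a", "a", "b", "c", "c", "c"), v = 1:6)
  d1 <- dedupe_repeat_tracks(rec, seed = 42)
  expect_equal(nrow(d1), 3)
  expect_identical(d1, dedupe_repeat_tracks(rec, seed = 42))
  expect_identical(dedupe_repeat_tracks(rec[!duplicated(rec$bird_id), ],
                                        seed = 1)$v, c(1L, 3L, 4L))
})
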