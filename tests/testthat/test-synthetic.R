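test_that("generators are pure functions of (config, seed)", {
  c1 <- generate_divide_cohort(25, seed = 8)
  c2 <- generate_divide_cohort(25, seed = 8)
  expect_identical(c1, c2)
  g1 <- generate_tracks(c1[1:4, ], seed = 9)
  g2 <- generate_tracks(c1[1:4, ], seed = 9)
  expect_identical(g1, g2)
  expect_identical(generate_arrivals(c1, seed = 10),
                   generate_arrivals(c1, seed = 10))
  expect_identical(generate_recoveries(seed = 11, n_random = 30),
                   generate_recoveries(seed = 11, n_random = 30))
  expect_false(identical(generate_divide_cohort(25, seed = 9)$breed_lon,
                         c1$breed_lon))
})

test_that("a noiseless cohort lies exactly on the cline curve", {
  cfg <- sim_config(cline = cline_params(14, 0.36, 245, 150, 1e-9))
  co <- generate_divide_cohort(30, cfg, seed = 3)
  expect_equal(co$direction_deg, normalize_bearing(co$true_direction),
               tolerance = 1e-6)
  # far west of the centre the mean direction approaches the western asymptote
  far <- generate_divide_cohort(10, cfg, seed = 4, lons = rep(12, 10))
  expect_true(all(abs(far$direction_deg - 245) < 0.01))
})

test_that("phenotype shares converge to the generator-implied expectation", {
  # law-of-large-numbers check: shares of an independent large sample lie
  # within 3 multinomial SEs of reference probabilities estimated at n = 2e4
  ref <- prop.table(table(generate_divide_cohort(20000, seed = 99)$phenotype))
  n <- 4000
  shares <- prop.table(table(generate_divide_cohort(n, seed = 12)$phenotype))
  for (p in names(ref)) {
    se <- sqrt(ref[[p]] * (1 - ref[[p]]) / n)
    expect_lt(abs(shares[[p]] - ref[[p]]), 3 * se + 0.005)
  }
  # inside the divide the intermediate phenotype is the modal strategy
  co <- generate_divide_cohort(6000, seed = 13)
  dv <- prop.table(table(co$phenotype[co$zone == "divide"]))
  expect_equal(names(which.max(dv)), "S")
  # directions span the SW-SE range without wrapping
  expect_true(all(co$direction_deg > 60 & co$direction_deg < 340))
})

test_that("noiseless tracks recover true crossing dates exactly", {
  cfg <- sim_config()
  co <- generate_divide_cohort(6, cfg, seed = 5)
  gt <- generate_tracks(co, cfg, seed = 6, noise = 0)
  tm <- timing_records(gt$tracks, co, seed = 7)
  for (v in c("t30", "t50", "t70")) {
    ok <- !is.na(tm[[v]])
    expect_gt(mean(ok), 0.5) # failures only via the equinox rule
    expect_equal(tm[[v]][ok], gt$truth[[v]][ok], tolerance = 1e-6)
  }
})

test_that("crossing estimates at study noise levels are accurate to about a day", {
  cfg <- sim_config()
  co <- generate_divide_cohort(30, cfg, seed = 15)
  gt <- generate_tracks(co, cfg, seed = 16)
  tm <- timing_records(gt$tracks, co, seed = 17, n_draws = 60)
  err <- c(tm$t30 - gt$truth$t30, tm$t50 - gt$truth$t50,
           tm$t70 - gt$truth$t70)
  err <- err[!is.na(err)]
  expect_gt(length(err), 30)
  expect_lte(median(abs(err)), 1)
  # tighter noise regime: the estimator concentrates within a day
  gt2 <- generate_tracks(co, cfg, seed = 16, noise = 0.3)
  tm2 <- timing_records(gt2$tracks, co, seed = 17, n_draws = 60)
  err2 <- c(tm2$t30 - gt2$truth$t30, tm2$t70 - gt2$truth$t70)
  err2 <- err2[!is.na(err2)]
  expect_gte(mean(abs(err2) <= 1), 0.85)
})

test_that("generated arrivals carry their ground-truth shifts", {
  co <- generate_divide_cohort(60, seed = 18)
  arr <- generate_arrivals(co, seed = 19)
  sh <- attr(arr, "shifts")
  expect_equal(unname(sh$arrival["SW"] - sh$arrival["S"]), 8.9)
  expect_equal(unname(sh$arrival["SW"] - sh$arrival["NW"]), 9.8)
  expect_equal(unname(sh$spring_start["SW"] - sh$spring_start["S"]), 14.6)
  # zero-SD models collapse each phenotype to a single date
  cfg0 <- sim_config(arrival = list(SW = arrival_gaussian(100, 0),
                                    SE = arrival_gaussian(100, 0),
                                    S = arrival_gaussian(91.1, 0),
                                    NW = arrival_gaussian(90.2, 0)))
  a0 <- generate_arrivals(co, cfg0, seed = 20)
  for (p in unique(as.character(a0$phenotype)))
    expect_equal(length(unique(a0$arrival_doy[a0$phenotype == p])), 1)
})

test_that("ground-truth columns round-trip through CSV bit-exactly", {
  co <- generate_divide_cohort(8, seed = 21)
  gt <- generate_tracks(co[1:3, ], seed = 22)
  path <- tempfile(fileext = ".csv")
  write_table(gt$truth, path)
  back <- utils::read.csv(path)
  for (v in c("t30", "t50", "t70", "distance_km"))
    expect_identical(back[[v]], gt$truth[[v]])
  unlink(path)
})

test_that("end-to-end cline recovery from a synthetic cohort", {
  # the pipeline's core property: cohort -> groups -> fit recovers the
  # generating cline within Monte-Carlo error
  ests <- t(vapply(1:12, function(r) {
    co <- generate_divide_cohort(120, seed = 400 + r)
    g <- make_groups(co$breed_lon, co$direction_deg, co$zone)
    f <- fit_cline(g, profile = FALSE, seed = r)
    c(f$params$center, f$params$width)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) - 14.0), 0.1)
  expect_lt(abs(mean(lon_width_to_km(ests[, 2], 47.6)) - 27) / 27, 0.5)
})
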