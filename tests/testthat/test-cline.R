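test_that("grouping partitions each zone into contiguous near-equal groups", {
  g <- make_groups(c(13.0, 13.1, 13.2, 13.3), c(200, 210, 190, 180),
                   rep("divide", 4), min_size = 2)
  expect_equal(g$n, c(2L, 2L))
  expect_equal(g$position, c(13.05, 13.25))
  expect_equal(g$mean_trait, c(205, 185))
  # 5 points, min 2 -> sizes {2, 3} with the larger group eastward
  g5 <- make_groups(seq(13, 13.4, by = 0.1), rep(200, 5), rep("divide", 5))
  expect_equal(g5$n, c(2L, 3L))
  # zones are never pooled
  gz <- make_groups(c(12, 12.1, 15, 15.1), rep(200, 4),
                    c("west", "west", "east", "east"))
  expect_equal(gz$zone, c("west", "east"))
  # a single zone of exactly min_size is one group; undersized zones warn
  expect_equal(nrow(make_groups(c(13, 13.1), c(1, 2), c("divide", "divide"))), 1)
  expect_warning(make_groups(c(13, 14, 14.1), c(1, 2, 3),
                             c("west", "divide", "divide")), "fewer than")
})

test_that("cline mean has the tanh sigmoid shape", {
  p <- cline_params(14, 0.36, 245, 150, 20)
  expect_equal(cline_mean(14, p), (245 + 150) / 2)
  expect_equal(cline_mean(-1e6, p), 245)
  expect_equal(cline_mean(1e6, p), 150)
  expect_equal(cline_mean(14 + 0.18, p), 245 + (1 + tanh(1)) / 2 * (150 - 245),
               tolerance = 1e-12)
  expect_equal((1 + tanh(1)) / 2, 0.88080, tolerance = 1e-5)
  # monotone when asymptotes differ (strict near the centre, flat only in
  # the numerically saturated tails)
  x <- seq(10, 18, by = 0.05)
  expect_true(all(diff(cline_mean(x, p)) <= 0))
  xc <- seq(13.5, 14.5, by = 0.05)
  expect_true(all(diff(cline_mean(xc, p)) < 0))
})

test_that("noiseless cline data are recovered essentially exactly", {
  p <- cline_params(14, 0.36, 245, 150, 20)
  fit <- fit_cline(noiseless_groups(p), profile = FALSE, seed = 2)
  expect_lt(abs(fit$params$center - 14), 1e-3)
  expect_lt(abs(fit$params$width - 0.36) / 0.36, 1e-2)
  expect_lt(abs(fit$params$mu_left - 245), 0.5)
  expect_lt(abs(fit$params$mu_right - 150), 0.5)
})

test_that("optimizer attains at least the best point of a dense grid scan", {
  p <- cline_params(13.7, 0.8, 240, 155, 20)
  set.seed(21)
  lons <- sort(runif(30, 12, 16))
  g <- data.frame(position = lons,
                  mean_trait = cline_mean(lons, p) + rnorm(30, 0, 6),
                  sd_trait = 6, n = 4)
  fit <- fit_cline(g, profile = FALSE, seed = 4)
  # 50x50 grid over (center, width), other params fixed at the MLE values
  centers <- seq(12, 16, length.out = 50)
  widths <- seq(0.05, 4, length.out = 50)
  ll <- function(th) sum(dnorm(g$mean_trait,
                               th[3] + (th[4] - th[3]) *
                                 (1 + tanh(2 * (g$position - th[1]) / th[2])) / 2,
                               th[5] / sqrt(g$n), log = TRUE))
  mle <- unlist(fit$params, use.names = FALSE)
  grid_best <- max(vapply(centers, function(cc)
    max(vapply(widths, function(w) ll(c(cc, w, mle[3], mle[4], mle[5])),
               numeric(1))), numeric(1)))
  expect_gte(fit$loglik + 1e-8, grid_best)
})

test_that("reflecting the transect mirrors the centre and keeps the width", {
  p <- cline_params(13.7, 0.6, 240, 155, 15)
  set.seed(31)
  lons <- sort(runif(24, 12, 16))
  tr <- cline_mean(lons, p) + rnorm(24, 0, 4)
  g <- data.frame(position = lons, mean_trait = tr, sd_trait = 4, n = 3)
  gr <- data.frame(position = -lons, mean_trait = tr, sd_trait = 4, n = 3)
  f1 <- fit_cline(g, profile = FALSE, seed = 6)
  f2 <- fit_cline(gr, profile = FALSE, seed = 6)
  expect_lt(abs(f2$params$center + f1$params$center), 0.02)
  expect_lt(abs(f2$params$width - f1$params$width), 0.02)
  expect_lt(abs(f2$params$mu_left - f1$params$mu_right), 0.5)
})

test_that("degenerate inputs are flagged or rejected", {
  flat <- data.frame(position = seq(12, 16, length.out = 10),
                     mean_trait = rep(200, 10), sd_trait = 0, n = 2)
  expect_warning(f <- fit_cline(flat, profile = FALSE, seed = 3),
                 "unidentifiable")
  expect_true("width_unidentifiable" %in% f$flags)
  same <- data.frame(position = rep(14, 6), mean_trait = rnorm(6, 200, 5),
                     sd_trait = 5, n = 2)
  expect_error(fit_cline(same, profile = FALSE), "identifiable")
  expect_error(fit_cline(flat[1:3, ], profile = FALSE), "at least 4")
})

test_that("support intervals match the quadratic closed form and flag boundaries", {
  cgrid <- seq(13, 15, length.out = 401)
  si <- support_interval(cgrid, -(cgrid - 14)^2 / 0.02, drop = 2)
  expect_equal(as.numeric(si), c(13.8, 14.2), tolerance = 1e-4)
  expect_true(all(attr(si, "bounded")))
  # flat profile spans the whole domain, flagged unbounded on both sides
  sflat <- support_interval(cgrid, rep(0, length(cgrid)))
  expect_equal(as.numeric(sflat), range(cgrid))
  expect_false(any(attr(sflat, "bounded")))
  # profile peaked at the right boundary: right endpoint open
  sright <- support_interval(cgrid, 10 * cgrid)
  expect_false(attr(sright, "bounded")[2])
  expect_true(attr(sright, "bounded")[1])
})

test_that("profile-likelihood support intervals bracket the point estimates", {
  p <- cline_params(14, 0.5, 245, 150, 20)
  set.seed(12)
  lons <- sort(c(seq(12, 16, length.out = 12), seq(13.6, 14.4, length.out = 12)))
  g <- data.frame(position = lons,
                  mean_trait = cline_mean(lons, p) + rnorm(24, 0, 5),
                  sd_trait = 5, n = 4)
  fit <- fit_cline(g, profile = TRUE, profile_points = 40, seed = 5)
  expect_true(fit$support_center[1] <= fit$params$center &&
                fit$params$center <= fit$support_center[2])
  expect_true(fit$support_width[1] <= fit$params$width &&
                fit$params$width <= fit$support_width[2])
})

test_that("longitudinal width converts to km by the cosine rule", {
  expect_equal(lon_width_to_km(1, 0), pi * 6371.0088 / 180, tolerance = 1e-9)
  expect_equal(lon_width_to_km(0, 47.6), 0)
  expect_equal(lon_width_to_km(0.36, 47.6), 27.0, tolerance = 0.01)
  expect_error(lon_width_to_km(1, 90), "< 90")
})
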