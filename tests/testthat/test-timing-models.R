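make_cohort_table <- function(ns, levels, shifts, sd, seed, base = 100) {
  set.seed(seed)
  n <- sum(ns)
  ph <- factor(rep(levels, ns), levels = c("SW", "S", "SE", "NW"))
  data.frame(phenotype = ph,
             arrival = base + shifts[as.character(ph)] + rnorm(n, 0, sd),
             breed_lat = runif(n, 46.6, 48.7),
             breed_lon = runif(n, 5, 20),
             year = sample(2014:2016, n, TRUE),
             sex = sample(c("M", "F"), n, TRUE))
}

test_that("a known group shift is recovered without bias", {
  est <- vapply(1:60, function(r) {
    d <- make_cohort_table(c(20, 20), c("SW", "SE"), c(SW = 7, SE = 0), 6,
                           seed = 100 + r)
    d$sex <- NULL
    fit_timing_model(d, "arrival", "SWvsSE")$contrast$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 7), 0.5)
})

test_that("identical group distributions give a near-zero contrast", {
  d <- make_cohort_table(c(25, 25), c("SW", "SE"), c(SW = 0, SE = 0), 6,
                         seed = 55)
  d$sex <- NULL
  ct <- fit_timing_model(d, "arrival", "SWvsSE")$contrast
  expect_lt(abs(ct$t), 3)
  expect_lt(abs(ct$estimate), 5)
})

test_that("zero-effect covariates are dropped by backward elimination", {
  # with year the only (null) covariate, the elimination rule retains it
  # exactly when its F-test p-value lands below 0.10 - about 10% of runs
  dropped_year <- vapply(1:200, function(r) {
    d <- make_cohort_table(c(20, 20), c("SW", "SE"), c(SW = 5, SE = 0), 6,
                           seed = 300 + r)
    "year" %in% fit_timing_model(d, "arrival", "SWvsSE",
                                 covariates = "year")$dropped
  }, logical(1))
  expect_gte(mean(dropped_year), 0.85)
  # the full covariate set still gets pruned in the clear majority of runs
  d <- make_cohort_table(c(20, 20), c("SW", "SE"), c(SW = 5, SE = 0), 6,
                         seed = 77)
  d$sex <- NULL
  fit <- fit_timing_model(d, "arrival", "SWvsSE")
  expect_true(all(fit$dropped %in% c("breed_lat", "breed_lon", "year")))
})

test_that("the S-vs-mean(SW,SE) contrast uses the right coefficients", {
  d <- make_cohort_table(c(10, 30, 12), c("SW", "S", "SE"),
                         c(SW = 0, S = -9, SE = 0), 0.001, seed = 4)
  d$sex <- NULL
  ct <- fit_timing_model(d, "arrival", "SvsSWSE",
                         covariates = character(0))$contrast
  expect_equal(ct$estimate, -9, tolerance = 1e-2)
  # df equals the residual df of the final model
  expect_equal(ct$df, sum(c(10, 30, 12)) - 3)
})

test_that("sex is admissible only in the NW-vs-SW comparison", {
  d <- make_cohort_table(c(15, 15), c("NW", "SW"), c(NW = -9.8, SW = 0), 6,
                         seed = 10)
  ct <- fit_timing_model(d, "arrival", "NWvsSW")
  expect_s3_class(ct, "timing_contrast")
  d2 <- make_cohort_table(c(15, 15), c("SW", "SE"), c(SW = 0, SE = 0), 6,
                          seed = 11)
  expect_error(fit_timing_model(d2, "arrival", "SWvsSE",
                                covariates = c("sex", "year")), "admissible")
})

test_that("log-transformed responses report ratio contrasts", {
  set.seed(13)
  d <- data.frame(phenotype = factor(rep(c("NW", "SW"), each = 20),
                                     levels = c("SW", "S", "SE", "NW")),
                  dur = exp(rnorm(40, log(10), 0.2) +
                              rep(c(log(0.4), 0), each = 20)))
  ct <- fit_timing_model(d, "dur", "NWvsSW", covariates = character(0),
                         log_response = TRUE)$contrast
  expect_true(all(c("ratio", "ratio_lower", "ratio_upper") %in% names(ct)))
  expect_equal(ct$ratio, 0.4, tolerance = 0.15)
  expect_error(fit_timing_model(transform(d, dur = dur - 20), "dur", "NWvsSW",
                                covariates = character(0),
                                log_response = TRUE), "positive")
})

test_that("rank-deficient designs fail loudly naming the collinear term", {
  d <- make_cohort_table(c(10, 10), c("SW", "SE"), c(SW = 0, SE = 0), 6,
                         seed = 14)
  d$dup <- d$breed_lat
  expect_error(fit_timing_model(d, "arrival", "SWvsSE",
                                covariates = c("breed_lat", "dup")),
               "collinear.*dup")
})

test_that("undersized groups are rejected", {
  d <- make_cohort_table(c(1, 10), c("SW", "SE"), c(SW = 0, SE = 0), 6,
                         seed = 15)
  expect_error(fit_timing_model(d, "arrival", "SWvsSE"), ">= 2")
})
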