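# Arrival-timing assortative-mating simulation.

#' Gaussian arrival-date model for one phenotype
#' @param mean mean arrival day of year.
#' @param sd SD of arrival day (>= 0).
#' @return list describing the model.
#' @export
arrival_gaussian <- function(mean, sd) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  list(type = "gaussian", mean = mean, sd = sd)
}

#' Empirical (kernel-density) arrival-date model for one phenotype
#'
#' Draws are generated by resampling the observed dates and adding Gaussian
#' noise with the kernel bandwidth (Silverman's rule by default), i.e.
#' sampling from the Gaussian KDE of the observations.
#'
#' @param samples observed arrival days of year.
#' @param bw bandwidth, or the name of a bandwidth rule accepted by
#'   [stats::density()] (default `"nrd0"`, Silverman).
#' @return list describing the model (the resolved numeric bandwidth is
#'   recorded in `bw_value`).
#' @export
arrival_kde <- function(samples, bw = "nrd0") {
  if (length(samples) < 2) stop("need >= 2 samples for a KDE", call. = FALSE)
  bw_value <- if (is.character(bw)) stats::density(samples, bw = bw)$bw else bw
  list(type = "kde", samples = samples, bw = bw, bw_value = bw_value)
}

.draw_arrivals <- function(model, n) {
  if (n == 0) return(numeric(0))
  switch(model$type,
         gaussian = stats::rnorm(n, model$mean, model$sd),
         kde = sample(model$samples, n, replace = TRUE) +
           stats::rnorm(n, 0, model$bw_value),
         stop("unknown arrival model type", call. = FALSE))
}

#' Configuration for the assortative-mating simulation
#'
#' Phenotype proportions may sum to less than 1 (within tolerance): the
#' remainder becomes an implicit `"other"` phenotype (e.g. the rare NW bird
#' inside the divide) that draws arrivals from `other_arrival` and never
#' counts as intermediate. Proportions summing to more than 1 are an error.
#'
#' @param proportions named numeric vector of phenotype relative abundances
#'   (all >= 0, sum <= 1).
#' @param arrivals named list of arrival models ([arrival_gaussian()] /
#'   [arrival_kde()]), one per phenotype in `proportions`.
#' @param n_birds birds per replicate (default 41).
#' @param delay_days presence window after a focal bird's arrival within
#'   which mates are available (default 5; pair formation happens within days
#'   of arrival and females arrive slightly later than males).
#' @param n_reps number of replicates (default 1000).
#' @param timing_dependent mate choice restricted to birds present within the
#'   delay window (`TRUE`) or uniform over all other birds (`FALSE`).
#' @param focal_phenotype phenotype whose like-with-like pairings are counted
#'   (default `"S"`).
#' @param other_arrival arrival model for the implicit remainder phenotype.
#' @return object of class `mating_config`.
#' @export
mating_config <- function(proportions = c(S = 0.537, SE = 0.268, SW = 0.171),
                          arrivals = list(
                            S = arrival_gaussian(91.1, 6),
                            SE = arrival_gaussian(100, 6),
                            SW = arrival_gaussian(100, 6)),
                          n_birds = 41, delay_days = 5, n_reps = 1000,
                          timing_dependent = TRUE, focal_phenotype = "S",
                          other_arrival = arrival_gaussian(100, 6)) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("proportions must be named by phenotype", call. = FALSE)
  if (any(proportions < 0)) stop("proportions must be >= 0", call. = FALSE)
  tot <- sum(proportions)
  if (tot > 1 + 1e-9) stop("proportions sum to more than 1", call. = FALSE)
  if (tot < 1 - 1e-9) {
    proportions <- c(proportions, other = unname(1 - tot))
    arrivals$other <- other_arrival
  }
  miss <- setdiff(names(proportions), names(arrivals))
  if (length(miss))
    stop("no arrival model for phenotype(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (delay_days < 0) stop("delay_days must be >= 0", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (n_birds < 2) stop("n_birds must be >= 2 to form pairs", call. = FALSE)
  structure(list(proportions = proportions, arrivals = arrivals,
                 n_birds = n_birds, delay_days = delay_days, n_reps = n_reps,
                 timing_dependent = timing_dependent,
                 focal_phenotype = focal_phenotype),
            class = "mating_config")
}

#' One replicate of the mating simulation
#'
#' Draws phenotype counts from Multinomial(`n_birds`, proportions), an
#' arrival date per bird from its phenotype's model, and then one directed
#' pairing per focal bird: the mate is drawn uniformly from all other birds
#' present within `delay_days` of the focal arrival (timing-dependent) or
#' from all other birds (timing-independent). If a focal bird's presence
#' window contains no other bird (possible only for the earliest arrival),
#' the earliest-arriving other bird is used.
#'
#' @param cfg a [mating_config()]. Uses the current RNG state; seed via
#'   [run_mating_sim()] or `set.seed()`.
#' @return proportion of the `n_birds` focal pairings in which both the focal
#'   bird and its mate carry the focal phenotype.
#' @export
simulate_replicate <- function(cfg) {
  counts <- stats::rmultinom(1, cfg$n_birds, cfg$proportions)[, 1]
  ph <- rep(names(counts), counts)
  arr <- numeric(cfg$n_birds)
  for (p in names(counts))
    arr[ph == p] <- .draw_arrivals(cfg$arrivals[[p]], counts[[p]])
  is_focal <- ph == cfg$focal_phenotype
  both <- logical(cfg$n_birds)
  ord <- order(arr)
  for (i in seq_len(cfg$n_birds)) {
    pool <- if (cfg$timing_dependent)
      which(arr <= arr[i] + cfg$delay_days & seq_len(cfg$n_birds) != i)
    else setdiff(seq_len(cfg$n_birds), i)
    if (!length(pool)) pool <- setdiff(ord, i)[1]
    mate <- pool[sample.int(length(pool), 1)]
    both[i] <- is_focal[i] && is_focal[mate]
  }
  mean(both)
}

#' Run the assortative-mating simulation
#'
#' @param cfg a [mating_config()].
#' @param seed integer seed; the whole run is reproducible from it.
#' @return object of class `mating_result`: per-replicate proportions
#'   (`props`), their `mean`, `sd` and central 95% interval (`ci`), and the
#'   configuration.
#' @export
run_mating_sim <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "mating_config"))
  set.seed(seed)
  props <- vapply(seq_len(cfg$n_reps), function(i) simulate_replicate(cfg),
                  numeric(1))
  structure(list(props = props, mean = mean(props), sd = stats::sd(props),
                 ci = unname(stats::quantile(props, c(0.025, 0.975))),
                 cfg = cfg, seed = seed),
            class = "mating_result")
}

#' @export
print.mating_result <- function(x, ...) {
  cat(sprintf("Assortative-mating simulation (%d replicates, n = %d birds, %s)\n",
              x$cfg$n_reps, x$cfg$n_birds,
              if (x$cfg$timing_dependent) "timing-dependent mate choice"
              else "timing-independent mate choice"))
  cat(sprintf("  both-%s pairings: mean %.1f%% (SD %.1f), 95%% interval [%.1f%%, %.1f%%]\n",
              x$cfg$focal_phenotype, 100 * x$mean, 100 * x$sd,
              100 * x$ci[1], 100 * x$ci[2]))
  invisible(x)
}
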