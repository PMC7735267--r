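# Migratory phenotype classification and per-bird summaries.

#' Winter-location classification rule
#'
#' Longitude/latitude cut-offs that map a wintering location to a migratory
#' phenotype. Defaults follow the field convention for the central-European
#' divide: north of `lat_split` the SW/S boundary sits at `west_cut_north`
#' (5 degrees E); south of it, longer routes need less westerly component to
#' reach the same longitude, so the boundary moves to `west_cut_south`
#' (0 degrees). Birds wintering at or above `nw_lat_min` (Britain and
#' similar) are NW migrants; no Mediterranean wintering site reaches it.
#'
#' @param lat_split latitude separating the two SW/S longitude cuts (deg N).
#' @param west_cut_north,west_cut_south SW/S longitude cut north resp. south
#'   of `lat_split` (deg E).
#' @param east_cut S/SE longitude cut (deg E).
#' @param nw_lat_min minimum wintering latitude for the NW label (deg N).
#' @return an object of class `classification_rule`.
#' @export
classification_rule <- function(lat_split = 37.5, west_cut_north = 5,
                                west_cut_south = 0, east_cut = 20,
                                nw_lat_min = 45) {
  if (west_cut_north >= east_cut || west_cut_south >= east_cut)
    stop("west cuts must be west of east_cut", call. = FALSE)
  structure(list(lat_split = lat_split, west_cut_north = west_cut_north,
                 west_cut_south = west_cut_south, east_cut = east_cut,
                 nw_lat_min = nw_lat_min),
            class = "classification_rule")
}

#' Phenotype labels in display order
#' @export
PHENOTYPE_LEVELS <- c("SW", "S", "SE", "NW")

#' Classify a wintering location into a migratory phenotype
#'
#' Deterministic, total classification: every finite coordinate maps to
#' exactly one of SW, S, SE, NW. Longitudes exactly on a cut belong to S
#' (the intermediate interval is closed, with a 1e-9 degree tolerance band
#' so labels are stable under sub-nanodegree perturbation of a boundary
#' value); latitudes exactly at `lat_split` use the northern cut.
#'
#' @param lat,lon wintering coordinates, decimal degrees (vectorised).
#' @param rule a [classification_rule()].
#' @return factor with levels SW, S, SE, NW.
#' @examples
#' classify_winter(40, 10)  # "S"
#' classify_winter(35, -3)  # "SW" (southern cut 0)
#' @export
classify_winter <- function(lat, lon, rule = classification_rule()) {
  .check_latlon(lat, lon, "wintering point")
  lon <- normalize_lon(lon)
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  eps <- 1e-9
  west_cut <- ifelse(lat >= rule$lat_split, rule$west_cut_north,
                     rule$west_cut_south)
  lab <- ifelse(lat >= rule$nw_lat_min, "NW",
                ifelse(lon < west_cut - eps, "SW",
                       ifelse(lon > rule$east_cut + eps, "SE", "S")))
  factor(lab, levels = PHENOTYPE_LEVELS)
}

#' Autumn migration direction of tracked birds
#'
#' Rhumb-line bearing from breeding to wintering site, the simplified route
#' representation that is robust to track nonlinearity and equinox bias.
#'
#' @param birds data.frame with columns `breed_lat`, `breed_lon`,
#'   `winter_lat`, `winter_lon`.
#' @return numeric vector of bearings in [0, 360).
#' @export
autumn_direction <- function(birds) {
  .require_cols(birds, c("breed_lat", "breed_lon", "winter_lat", "winter_lon"),
                "bird table")
  rhumb_bearing(birds$breed_lat, birds$breed_lon,
                birds$winter_lat, birds$winter_lon)
}

#' Phenotype and summarise a bird table
#'
#' Adds `phenotype` (from [classify_winter()]), `direction_deg` (rhumb
#' bearing breeding to wintering) and `distance_km` (great-circle) columns.
#'
#' @param birds data.frame with breeding/wintering coordinate columns.
#' @param rule a [classification_rule()].
#' @return the input with the three derived columns appended.
#' @export
phenotype_birds <- function(birds, rule = classification_rule()) {
  birds$phenotype <- classify_winter(birds$winter_lat, birds$winter_lon, rule)
  birds$direction_deg <- autumn_direction(birds)
  birds$distance_km <- great_circle_distance(birds$breed_lat, birds$breed_lon,
                                             birds$winter_lat, birds$winter_lon)
  birds
}

#' Pairwise Levene (Brown-Forsythe) tests of direction variance among sites
#'
#' Tests whether the spread of autumn migration directions differs between
#' breeding sites, site pair by site pair, with Benjamini-Hochberg adjustment
#' across pairs. By default directions enter as signed angular deviations
#' from their site's circular mean, which removes wrap-around artefacts;
#' `deviations = "raw"` uses the bearings as plain numbers.
#'
#' @param direction bearings in degrees.
#' @param site site label per bird (factor or character).
#' @param min_n minimum group size; smaller sites are excluded with a message.
#' @param deviations `"circular"` (default) or `"raw"`.
#' @return data.frame with one row per site pair: `site1`, `site2`,
#'   `F`, `df1`, `df2`, `p`, `p_adj`.
#' @export
levene_by_site <- function(direction, site, min_n = 5,
                           deviations = c("circular", "raw")) {
  deviations <- match.arg(deviations)
  site <- as.character(site)
  stopifnot(length(direction) == length(site))
  keep_sites <- names(which(table(site) >= min_n))
  dropped <- setdiff(unique(site), keep_sites)
  if (length(dropped))
    message("excluding sites below min_n = ", min_n, ": ",
            paste(dropped, collapse = ", "))
  if (length(keep_sites) < 2)
    stop("need at least two sites with >= min_n birds", call. = FALSE)
  ok <- site %in% keep_sites
  direction <- direction[ok]; site <- site[ok]
  y <- if (deviations == "circular") {
    ave(direction, site, FUN = function(d) angular_difference(d, circular_mean(d)))
  } else direction
  pairs <- utils::combn(sort(keep_sites), 2)
  res <- apply(pairs, 2, function(pr) {
    sel <- site %in% pr
    lt <- car::leveneTest(y[sel], factor(site[sel]))
    c(F = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
      p = lt[1, "Pr(>F)"])
  })
  out <- data.frame(site1 = pairs[1, ], site2 = pairs[2, ], t(res))
  names(out) <- c("site1", "site2", "F", "df1", "df2", "p")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Repeatability (intraclass correlation) from repeated tracks
#'
#' One-way ANOVA variance-components estimator of the proportion of total
#' variation explained by bird identity,
#' R = sigma2_id / (sigma2_id + sigma2_res), with the between-bird component
#' truncated at zero. The confidence interval comes from a seeded parametric
#' bootstrap: data are re-simulated from the fitted normal components on the
#' observed design and R re-estimated.
#'
#' @param value numeric measurements (e.g. direction, timing).
#' @param id bird identity per measurement.
#' @param n_boot bootstrap draws for the CI.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return object of class `repeatability_est`: list with `R`, `ci`,
#'   `var_id`, `var_res`, `n_ids`, `n_obs`.
#' @export
repeatability <- function(value, id, n_boot = 1000, conf = 0.95, seed = 1L) {
  id <- as.character(id)
  stopifnot(length(value) == length(id))
  ni <- table(id)
  if (length(ni) < 2) stop("need at least two individuals", call. = FALSE)
  if (all(ni < 2)) stop("no individual has repeated measures", call. = FALSE)
  est <- .anova_R(value, id)
  draws <- numeric(n_boot)
  set.seed(seed)
  ids <- rep(names(ni), ni)
  for (b in seq_len(n_boot)) {
    eff <- stats::rnorm(length(ni), 0, sqrt(est$var_id))
    names(eff) <- names(ni)
    sim <- eff[ids] + stats::rnorm(length(ids), 0, sqrt(est$var_res))
    draws[b] <- .anova_R(sim, ids)$R
  }
  alpha <- (1 - conf) / 2
  structure(list(R = est$R,
                 ci = unname(stats::quantile(draws, c(alpha, 1 - alpha))),
                 var_id = est$var_id, var_res = est$var_res,
                 n_ids = length(ni), n_obs = length(value), conf = conf),
            class = "repeatability_est")
}

# One-way ANOVA variance components (Sokal-Rohlf n0 for unbalanced designs)
.anova_R <- function(value, id) {
  id <- factor(id)
  k <- nlevels(id); N <- length(value)
  gm <- tapply(value, id, mean)
  ni <- tapply(value, id, length)
  ssb <- sum(ni * (gm - mean(value))^2)
  ssw <- sum((value - gm[id])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / max(1, N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_id <- max(0, (msb - msw) / n0)
  tot <- var_id + msw
  list(R = if (tot <= 0) 0 else var_id / tot, var_id = var_id, var_res = msw)
}

#' @export
print.repeatability_est <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f  [%0.2f, %0.2f] (%d%% parametric bootstrap)\n",
              x$R, x$ci[1], x$ci[2], round(100 * x$conf)))
  cat(sprintf("  %d individuals, %d observations; var(id) = %.3g, var(res) = %.3g\n",
              x$n_ids, x$n_obs, x$var_id, x$var_res))
  invisible(x)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(NULL)
}
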