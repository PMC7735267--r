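# Sigmoid geographic cline in migration direction: grouping, maximum-
# likelihood fit, profile-likelihood support intervals, width conversion.

#' Cline parameters
#'
#' Parameters of the tanh sigmoid cline
#' mu(x) = mu_left + (mu_right - mu_left) * (1 + tanh(2 (x - center) / width)) / 2,
#' where `center` is the inflection position, `width` the inverse of the
#' maximum slope (both in degrees longitude here), `mu_left`/`mu_right` the
#' western/eastern asymptotic trait values (degrees of bearing, treated as
#' linear) and `sigma` the individual trait SD around the cline mean.
#'
#' @param center cline centre (transect position, degrees longitude).
#' @param width cline width (> 0, same units as position).
#' @param mu_left,mu_right asymptotic trait means (degrees).
#' @param sigma individual trait SD (> 0, degrees).
#' @return object of class `cline_params`.
#' @export
cline_params <- function(center, width, mu_left, mu_right, sigma) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(center = center, width = width, mu_left = mu_left,
                 mu_right = mu_right, sigma = sigma),
            class = "cline_params")
}

#' Cline mean trait value at a transect position
#'
#' @param x transect position(s) (degrees longitude).
#' @param params a [cline_params()].
#' @return expected trait value(s), degrees.
#' @examples
#' p <- cline_params(14, 0.36, 245, 150, 20)
#' cline_mean(14, p)  # midpoint (245 + 150) / 2
#' @export
cline_mean <- function(x, params) {
  params$mu_left + (params$mu_right - params$mu_left) *
    (1 + tanh(2 * (x - params$center) / params$width)) / 2
}

#' Group individuals along the transect for cline fitting
#'
#' Within each zone (west of, inside, east of the divide — kept separate so
#' densely and sparsely sampled regions are never pooled), individuals sorted
#' by longitude are partitioned into contiguous groups of at least `min_size`
#' members, with sizes as equal as possible; when sizes must differ, larger
#' groups sit to the east. A zone with fewer than `min_size` individuals
#' becomes a single group, with a warning.
#'
#' @param lon individual transect positions (degrees longitude).
#' @param direction individual trait values (degrees).
#' @param zone zone label per individual (e.g. "west", "divide", "east").
#' @param min_size minimum group size (default 2).
#' @return data.frame ordered by position: `zone`, `position` (mean
#'   longitude), `mean_trait`, `sd_trait` (0 for singleton groups), `n`.
#' @export
make_groups <- function(lon, direction, zone, min_size = 2) {
  stopifnot(length(lon) == length(direction), length(lon) == length(zone))
  out <- do.call(rbind, lapply(split(seq_along(lon), as.character(zone)),
                               function(idx) {
    o <- idx[order(lon[idx])]
    n <- length(o)
    if (n < min_size) {
      warning("zone '", zone[o[1]], "' has fewer than min_size individuals; ",
              "kept as a single group", call. = FALSE)
      sizes <- n
    } else {
      g <- n %/% min_size
      base <- n %/% g
      extra <- n - g * base
      sizes <- c(rep(base, g - extra), rep(base + 1, extra))
    }
    grp <- rep(seq_along(sizes), sizes)
    data.frame(
      zone = zone[o[1]],
      position = tapply(lon[o], grp, mean),
      mean_trait = tapply(direction[o], grp, mean),
      sd_trait = vapply(split(direction[o], grp),
                        function(v) if (length(v) > 1) stats::sd(v) else 0,
                        numeric(1)),
      n = as.integer(tapply(lon[o], grp, length)),
      row.names = NULL)
  }))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cline_loglik <- function(theta, groups) {
  center <- theta[1]; width <- theta[2]
  mu_l <- theta[3]; mu_r <- theta[4]; sigma <- theta[5]
  mu <- mu_l + (mu_r - mu_l) * (1 + tanh(2 * (groups$position - center) / width)) / 2
  sum(stats::dnorm(groups$mean_trait, mu, sigma / sqrt(groups$n), log = TRUE))
}

.default_bounds <- function(groups) {
  pr <- range(groups$position)
  span <- diff(pr)
  if (span <= 0) stop("cline not identifiable: all positions equal", call. = FALSE)
  tr <- range(groups$mean_trait)
  margin <- max(1, 0.5 * diff(tr))
  pooled <- stats::sd(groups$mean_trait) * sqrt(mean(groups$n))
  list(lower = c(pr[1], span * 1e-3, tr[1] - margin, tr[1] - margin, 1e-3),
       upper = c(pr[2], span, tr[2] + margin, tr[2] + margin,
                 max(5 * pooled, 1)))
}

#' Fit a sigmoid cline to grouped trait data by maximum likelihood
#'
#' Maximises the Gaussian log-likelihood of group mean traits, each
#' distributed Normal(mu(x), sigma / sqrt(n)) around the tanh cline, over
#' (center, width, mu_left, mu_right, sigma) with box constraints and
#' multiple seeded starts (one data-driven start plus `n_starts - 1` random
#' starts). With `profile = TRUE`, profile log-likelihoods over centre and
#' width are computed and two-log-likelihood-unit support intervals
#' extracted.
#'
#' @param groups data.frame from [make_groups()] (columns `position`,
#'   `mean_trait`, `n`); at least 4 groups.
#' @param bounds optional list with `lower`/`upper` length-5 numeric vectors
#'   in parameter order (center, width, mu_left, mu_right, sigma). Defaults:
#'   centre within the position range, width within the position span,
#'   asymptotes within the trait range plus a margin.
#' @param n_starts number of optimisation starts.
#' @param seed integer seed for the random starts.
#' @param profile compute profile likelihoods and support intervals?
#' @param profile_points grid size per profiled parameter.
#' @param drop log-likelihood drop defining the support interval (default 2).
#' @return object of class `cline_fit`: `params` ([cline_params()]),
#'   `loglik`, `support_center`, `support_width` (with `bounded`
#'   attributes), `profile_center`, `profile_width` (data.frames), `flags`,
#'   and the input `groups`.
#' @export
fit_cline <- function(groups, bounds = NULL, n_starts = 5, seed = 1L,
                      profile = TRUE, profile_points = 60, drop = 2) {
  .require_cols(groups, c("position", "mean_trait", "n"), "group table")
  if (nrow(groups) < 4) stop("need at least 4 groups", call. = FALSE)
  if (is.null(bounds)) bounds <- .default_bounds(groups)
  lower <- bounds$lower; upper <- bounds$upper
  if (diff(range(groups$position)) <= 0)
    stop("cline not identifiable: all positions equal", call. = FALSE)

  # data-driven start: asymptotes from the transect thirds
  pr <- range(groups$position)
  lo_third <- groups$mean_trait[groups$position <= pr[1] + diff(pr) / 3]
  hi_third <- groups$mean_trait[groups$position >= pr[2] - diff(pr) / 3]
  start0 <- c(mean(pr), diff(pr) / 4,
              mean(lo_third), mean(hi_third),
              max(stats::sd(groups$mean_trait), 1))
  start0 <- pmin(pmax(start0, lower), upper)

  set.seed(seed)
  starts <- rbind(start0,
                  matrix(stats::runif((n_starts - 1) * 5, lower, upper),
                         ncol = 5, byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- try(stats::optim(starts[i, ], .cline_loglik, groups = groups,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(fnscale = -1, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  if (is.null(best)) stop("cline optimisation failed from every start", call. = FALSE)

  th <- best$par
  flags <- character(0)
  if (abs(th[4] - th[3]) < 1e-3 * th[5]) {
    flags <- c(flags, "width_unidentifiable")
    warning("asymptotes coincide: cline width is unidentifiable", call. = FALSE)
  }
  params <- cline_params(th[1], th[2], th[3], th[4], th[5])

  fit <- structure(list(params = params, loglik = best$value,
                        convergence = best$convergence, flags = flags,
                        support_center = NULL, support_width = NULL,
                        profile_center = NULL, profile_width = NULL,
                        bounds = bounds, groups = groups),
                   class = "cline_fit")
  if (profile) {
    fit$profile_center <- profile_cline(fit, "center", n = profile_points)
    fit$profile_width <- profile_cline(fit, "width", n = profile_points)
    fit$support_center <- support_interval(fit$profile_center$value,
                                           fit$profile_center$loglik, drop)
    fit$support_width <- support_interval(fit$profile_width$value,
                                          fit$profile_width$loglik, drop)
  }
  fit
}

#' Profile log-likelihood of one cline parameter
#'
#' Fixes `param` on a grid and re-maximises the likelihood over the
#' remaining four parameters at each grid point, starting from the MLE.
#'
#' @param fit a `cline_fit`.
#' @param param `"center"` or `"width"`.
#' @param n grid size.
#' @return data.frame with columns `value`, `loglik`.
#' @export
profile_cline <- function(fit, param = c("center", "width"), n = 60) {
  param <- match.arg(param)
  idx <- if (param == "center") 1L else 2L
  lower <- fit$bounds$lower; upper <- fit$bounds$upper
  mle <- unlist(fit$params, use.names = FALSE)
  grid <- sort(unique(c(seq(lower[idx], upper[idx], length.out = n), mle[idx])))
  free <- setdiff(1:5, idx)
  ll <- vapply(grid, function(v) {
    obj <- function(th4) {
      th <- numeric(5); th[idx] <- v; th[free] <- th4
      .cline_loglik(th, fit$groups)
    }
    opt <- try(stats::optim(mle[free], obj, method = "L-BFGS-B",
                            lower = lower[free], upper = upper[free],
                            control = list(fnscale = -1, maxit = 300)),
               silent = TRUE)
    if (inherits(opt, "try-error")) -Inf else opt$value
  }, numeric(1))
  data.frame(value = grid, loglik = ll)
}

#' Support interval from a likelihood profile
#'
#' Smallest interval containing every parameter value whose profile
#' log-likelihood is within `drop` units of the maximum; endpoints by linear
#' interpolation between grid points. If the profile is still above the
#' threshold at a grid boundary, that side is flagged unbounded (attribute
#' `bounded`).
#'
#' @param value grid of parameter values (increasing).
#' @param loglik profile log-likelihood at each grid value.
#' @param drop log-likelihood drop (default 2).
#' @return numeric length-2 interval with attribute `bounded`
#'   (logical length 2).
#' @export
support_interval <- function(value, loglik, drop = 2) {
  stopifnot(length(value) == length(loglik), length(value) >= 2)
  o <- order(value)
  value <- value[o]; loglik <- loglik[o]
  thr <- max(loglik) - drop
  above <- loglik >= thr
  if (!any(above)) stop("no profile point within the drop of the maximum",
                        call. = FALSE)
  i1 <- which(above)[1]; i2 <- rev(which(above))[1]
  bounded <- c(TRUE, TRUE)
  if (i1 == 1) { lo <- value[1]; bounded[1] <- FALSE } else {
    lo <- value[i1 - 1] + (thr - loglik[i1 - 1]) /
      (loglik[i1] - loglik[i1 - 1]) * (value[i1] - value[i1 - 1])
  }
  if (i2 == length(value)) { hi <- value[i2]; bounded[2] <- FALSE } else {
    hi <- value[i2] + (thr - loglik[i2]) /
      (loglik[i2 + 1] - loglik[i2]) * (value[i2 + 1] - value[i2])
  }
  structure(c(lo, hi), bounded = bounded)
}

#' Convert a longitudinal cline width to kilometres
#'
#' Width fitted in degrees longitude scaled by the local length of a degree
#' of longitude at the transect latitude.
#'
#' @param width_deg width in degrees longitude.
#' @param transect_lat latitude of the transect (|lat| < 90).
#' @return width in km.
#' @examples
#' lon_width_to_km(0.36, 47.6) # ~27 km
#' @export
lon_width_to_km <- function(width_deg, transect_lat) {
  if (any(abs(transect_lat) >= 90))
    stop("|transect_lat| must be < 90", call. = FALSE)
  width_deg * KM_PER_DEG * cos(.deg2rad(transect_lat))
}

#' @export
print.cline_fit <- function(x, ...) {
  p <- x$params
  cat("Sigmoid cline fit (maximum likelihood)\n")
  cat(sprintf("  centre  %.3f", p$center))
  if (!is.null(x$support_center))
    cat(sprintf("   2LL support [%.3f, %.3f]", x$support_center[1],
                x$support_center[2]))
  cat("\n")
  cat(sprintf("  width   %.3f", p$width))
  if (!is.null(x$support_width))
    cat(sprintf("   2LL support [%.3f, %.3f]", x$support_width[1],
                x$support_width[2]))
  cat("\n")
  cat(sprintf("  asymptotes %.1f -> %.1f deg; sigma %.2f deg\n",
              p$mu_left, p$mu_right, p$sigma))
  cat(sprintf("  log-likelihood %.3f over %d groups\n", x$loglik,
              nrow(x$groups)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
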