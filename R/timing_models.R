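# Linear timing-contrast models with backward elimination of covariates.

#' Timing contrast model
#'
#' Ordinary least squares model of a timing variable on migratory phenotype
#' plus nuisance covariates, with backward elimination: the covariate with
#' the largest F-test p-value above `drop_threshold` is removed and the model
#' refit, repeatedly; the phenotype factor itself is never dropped. Three
#' phenotype comparisons are supported:
#' \describe{
#'   \item{`SWvsSE`}{SW minus SE, within the divide.}
#'   \item{`SvsSWSE`}{intermediate S minus the mean of SW and SE.}
#'   \item{`NWvsSW`}{British winterers minus SW migrants; `sex` is an
#'     admissible covariate only here (the divide comparisons are all-male).}
#' }
#' Right-skewed responses (duration, speed) can be log-transformed, in which
#' case the contrast is additionally reported back-transformed as a ratio.
#'
#' @param data data.frame with a `phenotype` factor, the response column and
#'   any covariate columns present.
#' @param response name of the response column.
#' @param comparison one of `"SWvsSE"`, `"SvsSWSE"`, `"NWvsSW"`.
#' @param covariates covariate column names to start from; defaults to those
#'   of `breed_lat`, `breed_lon`, `year` (plus `sex` for `NWvsSW`) present in
#'   `data`.
#' @param drop_threshold p-value above which a covariate is eliminated
#'   (default 0.10).
#' @param log_response log-transform the response before fitting?
#' @return list of class `timing_contrast`: `contrast` (data.frame with
#'   `estimate`, `SE`, `df`, `t`, `p`, `lower`, `upper`, and `ratio` bounds
#'   when log-transformed), `model` (the final `lm`), `dropped`, `retained`.
#' @export
fit_timing_model <- function(data, response,
                             comparison = c("SWvsSE", "SvsSWSE", "NWvsSW"),
                             covariates = NULL, drop_threshold = 0.10,
                             log_response = FALSE) {
  comparison <- match.arg(comparison)
  .require_cols(data, c("phenotype", response), "timing table")
  wanted <- switch(comparison,
                   SWvsSE = c("SW", "SE"),
                   SvsSWSE = c("S", "SW", "SE"),
                   NWvsSW = c("NW", "SW"))
  d <- data[as.character(data$phenotype) %in% wanted, , drop = FALSE]
  d$phenotype <- factor(as.character(d$phenotype), levels = wanted)
  cnt <- table(d$phenotype)
  if (any(cnt < 2))
    stop("each compared phenotype needs >= 2 birds; got ",
         paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "),
         call. = FALSE)
  if (is.null(covariates)) {
    covariates <- intersect(c("breed_lat", "breed_lon", "year"), names(d))
    if (comparison == "NWvsSW") covariates <- c(covariates,
                                                intersect("sex", names(d)))
  }
  if ("sex" %in% covariates && comparison != "NWvsSW")
    stop("sex is an admissible covariate only for the NWvsSW comparison",
         call. = FALSE)

  y <- d[[response]]
  if (log_response) {
    if (any(y <= 0)) stop("log transform needs a strictly positive response",
                          call. = FALSE)
    d$.resp <- log(y)
  } else d$.resp <- y
  d <- d[stats::complete.cases(d[c(".resp", "phenotype", covariates)]), ,
         drop = FALSE]

  current <- covariates
  dropped <- character(0)
  repeat {
    form <- stats::reformulate(c("phenotype", current), response = ".resp")
    fit <- stats::lm(form, data = d)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient design; collinear term(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    if (!length(current)) break
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]]
    names(pv) <- rownames(dr)
    pv <- pv[names(pv) %in% current]
    if (!length(pv) || max(pv, na.rm = TRUE) <= drop_threshold) break
    worst <- names(which.max(pv))
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }

  emm <- emmeans::emmeans(fit, "phenotype")
  lev <- summary(emm)$phenotype
  coefs <- switch(comparison,
                  SWvsSE = stats::setNames(c(1, -1)[match(lev, c("SW", "SE"))], lev),
                  SvsSWSE = stats::setNames(c(1, -0.5, -0.5)[match(lev, c("S", "SW", "SE"))], lev),
                  NWvsSW = stats::setNames(c(1, -1)[match(lev, c("NW", "SW"))], lev))
  ct <- summary(emmeans::contrast(emm, method = stats::setNames(
    list(unname(coefs)), comparison)), infer = c(TRUE, TRUE))
  contrast <- data.frame(comparison = comparison, response = response,
                         estimate = ct$estimate, SE = ct$SE, df = ct$df,
                         t = ct$t.ratio, p = ct$p.value,
                         lower = ct$lower.CL, upper = ct$upper.CL)
  if (log_response) {
    contrast$ratio <- exp(contrast$estimate)
    contrast$ratio_lower <- exp(contrast$lower)
    contrast$ratio_upper <- exp(contrast$upper)
  }
  structure(list(contrast = contrast, model = fit, dropped = dropped,
                 retained = current, log_response = log_response),
            class = "timing_contrast")
}

#' @export
print.timing_contrast <- function(x, ...) {
  ct <- x$contrast
  cat(sprintf("%s contrast on %s%s\n", ct$comparison, ct$response,
              if (x$log_response) " (log scale)" else ""))
  cat(sprintf("  estimate %.2f (SE %.2f), t_%d = %.2f, p = %.3g, 95%% CI [%.2f, %.2f]\n",
              ct$estimate, ct$SE, round(ct$df), ct$t, ct$p, ct$lower, ct$upper))
  if (x$log_response)
    cat(sprintf("  as ratio: %.2fx [%.2f, %.2f]\n", ct$ratio, ct$ratio_lower,
                ct$ratio_upper))
  if (length(x$dropped))
    cat("  dropped covariates:", paste(x$dropped, collapse = ", "), "\n")
  if (length(x$retained))
    cat("  retained covariates:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
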