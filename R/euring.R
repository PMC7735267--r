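# Ringing-recovery filter: directed southward movements from the breeding
# region, selected on encounter location, seasonal windows, bearing and
# distance.

#' Recovery filter criteria
#'
#' Defaults select blackcap recoveries representing directed autumn movements
#' from the Austrian breeding region: first encounter inside the breeding box
#' during the breeding season, re-encounter during the migration/wintering
#' season, movement between 100 and 270 degrees (inclusive) of at least
#' 500 km. Seasonal windows compare month and day only, so records from any
#' year qualify; the recovery window wraps the year end.
#'
#' @param box_lon_min,box_lon_max,box_lat_min,box_lat_max breeding box (deg).
#' @param breeding_start,breeding_end breeding window, `"MM-DD"` strings.
#' @param recovery_start,recovery_end recovery window, `"MM-DD"` strings;
#'   wraps the year end when start > end.
#' @param bearing_min,bearing_max inclusive rhumb-bearing range (deg).
#' @param min_distance_km minimum great-circle displacement (km).
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(box_lon_min = 8, box_lon_max = 20,
                            box_lat_min = 46.6, box_lat_max = 48.7,
                            breeding_start = "05-15", breeding_end = "08-15",
                            recovery_start = "10-01", recovery_end = "05-01",
                            bearing_min = 100, bearing_max = 270,
                            min_distance_km = 500) {
  structure(list(box_lon_min = box_lon_min, box_lon_max = box_lon_max,
                 box_lat_min = box_lat_min, box_lat_max = box_lat_max,
                 breeding_start = breeding_start, breeding_end = breeding_end,
                 recovery_start = recovery_start, recovery_end = recovery_end,
                 bearing_min = bearing_min, bearing_max = bearing_max,
                 min_distance_km = min_distance_km),
            class = "filter_criteria")
}

.md_num <- function(x) {
  if (inherits(x, "Date") || all(grepl("^\\d{4}-", x)))
    x <- format(as.Date(x), "%m-%d")
  p <- strsplit(x, "-", fixed = TRUE)
  vapply(p, function(v) as.integer(v[1]) * 100L + as.integer(v[2]), integer(1))
}

.in_md_window <- function(dates, start, end) {
  md <- .md_num(dates); s <- .md_num(start); e <- .md_num(end)
  if (s <= e) md >= s & md <= e else md >= s | md <= e
}

#' Evaluate the recovery filter on one record
#'
#' @param record one-row data.frame (or list) with `date1`, `lat1`, `lon1`
#'   (first encounter) and `date2`, `lat2`, `lon2` (re-encounter).
#' @param criteria a [filter_criteria()].
#' @return list with `pass` (logical) and `reasons` (character vector naming
#'   every failed criterion; empty when passing).
#' @export
passes_filter <- function(record, criteria = filter_criteria()) {
  ev <- .evaluate_recoveries(as.data.frame(record), criteria)
  list(pass = ev$pass, reasons = if (ev$pass) character(0)
       else strsplit(ev$reasons, ";", fixed = TRUE)[[1]])
}

.CRITERIA <- c("breeding_box", "breeding_window", "recovery_window",
               "bearing", "distance")

.evaluate_recoveries <- function(records, criteria) {
  .require_cols(records, c("date1", "lat1", "lon1", "date2", "lat2", "lon2"),
                "recovery table")
  d1 <- as.Date(records$date1); d2 <- as.Date(records$date2)
  if (any(is.na(d1) | is.na(d2)))
    stop("malformed date in recovery record(s): row ",
         paste(which(is.na(d1) | is.na(d2)), collapse = ", "), call. = FALSE)
  bad <- !is.finite(records$lat1) | !is.finite(records$lon1) |
    !is.finite(records$lat2) | !is.finite(records$lon2) |
    abs(records$lat1) > 90 | abs(records$lat2) > 90
  if (any(bad))
    stop("malformed coordinates in recovery record(s): row ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (any(d2 <= d1))
    stop("re-encounter not after first encounter: row ",
         paste(which(d2 <= d1), collapse = ", "), call. = FALSE)
  lon1 <- normalize_lon(records$lon1)
  ok <- data.frame(
    breeding_box = lon1 >= criteria$box_lon_min & lon1 <= criteria$box_lon_max &
      records$lat1 >= criteria$box_lat_min & records$lat1 <= criteria$box_lat_max,
    breeding_window = .in_md_window(d1, criteria$breeding_start,
                                    criteria$breeding_end),
    recovery_window = .in_md_window(d2, criteria$recovery_start,
                                    criteria$recovery_end))
  same <- records$lat1 == records$lat2 &
    normalize_lon(records$lon1) == normalize_lon(records$lon2)
  bearing <- rep(NA_real_, nrow(records))
  if (any(!same))
    bearing[!same] <- rhumb_bearing(records$lat1[!same], records$lon1[!same],
                                    records$lat2[!same], records$lon2[!same])
  ok$bearing <- !same & bearing >= criteria$bearing_min &
    bearing <= criteria$bearing_max
  ok$distance <- great_circle_distance(records$lat1, records$lon1,
                                       records$lat2, records$lon2) >=
    criteria$min_distance_km
  pass <- Reduce(`&`, ok)
  reasons <- apply(ok, 1, function(r) paste(.CRITERIA[!r], collapse = ";"))
  data.frame(pass = pass, reasons = reasons, ok)
}

#' Filter a table of ringing recoveries
#'
#' Applies [passes_filter()] to every record. Records sharing a ring id
#' (multiple re-encounters of the same bird) are evaluated independently and
#' a ring is retained if any of its records passes; the audit counts
#' failures criterion by criterion at the record level, each record counted
#' once per criterion it fails.
#'
#' @param records data.frame with columns `ring_id`, `date1`, `lat1`, `lon1`,
#'   `date2`, `lat2`, `lon2`.
#' @param criteria a [filter_criteria()].
#' @return list: `retained` (passing records), `audit` (named integer vector
#'   of failure counts per criterion plus `n_input`, `n_pass`, `n_fail`),
#'   `evaluations` (per-record verdicts and reasons).
#' @export
filter_recoveries <- function(records, criteria = filter_criteria()) {
  if (nrow(records) == 0) {
    audit <- stats::setNames(integer(length(.CRITERIA)), .CRITERIA)
    return(list(retained = records,
                audit = c(audit, n_input = 0L, n_pass = 0L, n_fail = 0L),
                evaluations = cbind(records,
                                    pass = logical(0), reasons = character(0))))
  }
  ev <- .evaluate_recoveries(records, criteria)
  fails <- vapply(.CRITERIA, function(cr) sum(!ev[[cr]]), integer(1))
  retained <- records[ev$pass, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       audit = c(fails, n_input = nrow(records), n_pass = sum(ev$pass),
                 n_fail = sum(!ev$pass)),
       evaluations = cbind(records[, intersect("ring_id", names(records)),
                                   drop = FALSE],
                           ev[c("pass", "reasons")]))
}
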