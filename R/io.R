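# CSV schema readers/writers and GeoJSON track export.

.read_csv_checked <- function(path, required, what, date_cols = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, required, paste0(what, " (", path, ")"))
  for (col in intersect(date_cols, names(df))) {
    parsed <- as.Date(as.character(df[[col]]), format = "%Y-%m-%d")
    if (any(is.na(parsed) & !is.na(df[[col]])))
      stop(what, " (", path, "): unparseable date in column '", col,
           "', row ", paste(which(is.na(parsed) & !is.na(df[[col]])),
                            collapse = ", "), call. = FALSE)
    df[[col]] <- parsed
  }
  df
}

#' Read a bird summary table from CSV
#'
#' Expected columns: `bird_id`, `year`, `breed_lat`, `breed_lon`,
#' `winter_lat`, `winter_lon`; `sex` and `region` are optional.
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_bird_table <- function(path) {
  .read_csv_checked(path, c("bird_id", "year", "breed_lat", "breed_lon",
                            "winter_lat", "winter_lon"), "bird table")
}

#' Read a track-sample table from CSV
#'
#' Expected columns: `bird_id`, `date` (ISO), `lat`, `lon`; `season` and
#' `spread_km` are optional.
#' @param path CSV file path.
#' @return data.frame with `date` parsed to Date.
#' @export
read_track_table <- function(path) {
  .read_csv_checked(path, c("bird_id", "date", "lat", "lon"), "track table",
                    date_cols = "date")
}

#' Read a ringing-recovery table from CSV
#'
#' Minimal EURING-style mapping: one row per (ring, re-encounter) with
#' columns `ring_id`, `date1`, `lat1`, `lon1` (ringing encounter) and
#' `date2`, `lat2`, `lon2` (re-encounter), dates ISO.
#' @param path CSV file path.
#' @return data.frame with dates parsed.
#' @export
read_recovery_table <- function(path) {
  .read_csv_checked(path, c("ring_id", "date1", "lat1", "lon1",
                            "date2", "lat2", "lon2"),
                    "recovery table", date_cols = c("date1", "date2"))
}

#' Write a data.frame to CSV (no row names)
#'
#' Double columns are written with 17 significant digits so numeric
#' ground-truth values round-trip through CSV bit-exactly.
#'
#' @param df data.frame.
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]]) && !inherits(out[[col]], "Date"))
      out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export tracks as a GeoJSON FeatureCollection of LineStrings
#'
#' One LineString per bird, for quick visual inspection in any GIS viewer.
#'
#' @param tracks data.frame with `bird_id`, `date`, `lat`, `lon`.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
tracks_to_geojson <- function(tracks, path) {
  .require_cols(tracks, c("bird_id", "date", "lat", "lon"), "track table")
  feats <- lapply(split(tracks, tracks$bird_id), function(tr) {
    tr <- tr[order(tr$date), ]
    list(type = "Feature",
         properties = list(bird_id = tr$bird_id[1],
                           start = as.character(min(tr$date)),
                           end = as.character(max(tr$date))),
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(tr)),
                                  function(i) c(tr$lon[i], tr$lat[i])))))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
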