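# CSV / GeoJSON writers. Readers live in event_data.R next to the types.

#' Write an event table to CSV
#'
#' Writes the canonical column layout so that [read_events()] with the
#' default schema round-trips the table exactly.
#'
#' @param events An `event_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(events)
  df$period_start <- format(df$period_start, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an event series to CSV
#'
#' @param series An `event_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "event_series"))
  df <- data.frame(
    country = attr(series, "country"),
    resolution = attr(series, "resolution"),
    statistic = attr(series, "statistic"),
    period = format(series$period, "%Y-%m-%d"),
    value = series$value
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export georeferenced events as GeoJSON points
#'
#' One point feature per event carrying `country`, `fish_lost` and
#' `period_start` properties, for use in external mapping tools.
#' Events without coordinates are skipped (with a message).
#'
#' @param events An `event_table`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  has_coord <- !is.na(events$latitude) & !is.na(events$longitude)
  if (any(!has_coord)) {
    inform(sprintf("export_geojson: skipping %d event(s) without coordinates",
                   sum(!has_coord)))
  }
  ev <- events[has_coord, , drop = FALSE]
  features <- lapply(seq_len(nrow(ev)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(ev$longitude[i], ev$latitude[i])),
      properties = list(country = ev$country[i],
                        fish_lost = ev$fish_lost[i],
                        period_start = format(ev$period_start[i], "%Y-%m-%d"))
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
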