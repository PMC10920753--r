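# Domain types and ingestion for mortality-event records.
#
# An `event_table` is a tibble of mortality events, one row per reported
# loss record, with columns country, unit_id, period_start (Date),
# resolution (submonthly/monthly/yearly), fish_lost, and optional
# latitude/longitude. Provenance (source file, accepted/rejected row
# counts) travels as attributes.

#' Build a validated table of mortality events
#'
#' Constructs the central `event_table` container from a data frame of
#' mortality records. Records are validated (non-negative integral fish
#' counts, parseable dates, known reporting resolution); yearly records
#' are anchored to January 1 and sub-monthly records binned to the first
#' of their month, so all downstream aggregation works on a monthly or
#' yearly grain.
#'
#' @param x A data frame with columns `country`, `unit_id`,
#'   `period_start` (Date or ISO-8601 character), `resolution` (one of
#'   `"submonthly"`, `"monthly"`, `"yearly"`), `fish_lost`
#'   (non-negative integer), and optionally `latitude`, `longitude`.
#' @param allow_duplicates Keep exact duplicate
#'   (country, unit_id, period_start, fish_lost) rows. Defaults to
#'   `FALSE` because public collations often double-report events;
#'   duplicates are then rejected (reported, not silently dropped).
#' @param source Provenance label stored on the result.
#'
#' @return An `event_table`: a tibble with the columns above plus
#'   attributes `source` and `n_source_rows`, and a `rejected`
#'   attribute holding any rejected rows with row numbers and reasons.
#' @examples
#' ev <- event_table(data.frame(
#'   country = "Canada", unit_id = "site-1",
#'   period_start = as.Date("2015-01-01"),
#'   resolution = "monthly", fish_lost = 10000L
#' ))
#' total_mortality(ev)
#' @export
event_table <- function(x, allow_duplicates = FALSE, source = "in-memory") {
  required <- c("country", "unit_id", "period_start", "resolution", "fish_lost")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "salmonmme_schema_error")
  }
  x <- tibble::as_tibble(x)
  n_source <- nrow(x)
  x$.row <- seq_len(max(n_source, 0L))

  reasons <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad <- bad & is.na(reasons)
    reasons[bad] <<- why
  }

  if (!inherits(x$period_start, "Date")) {
    parsed <- as.Date(as.character(x$period_start), format = "%Y-%m-%d")
    flag(is.na(parsed) & !is.na(x$period_start), "unparseable period_start")
    flag(is.na(x$period_start), "missing period_start")
    x$period_start <- parsed
  } else {
    flag(is.na(x$period_start), "missing period_start")
  }
  flag(!(x$resolution %in% .RESOLUTIONS), "unknown resolution")
  fish <- suppressWarnings(as.numeric(x$fish_lost))
  flag(is.na(fish), "non-numeric fish_lost")
  flag(!is.na(fish) & fish < 0, "negative fish_lost")
  flag(!is.na(fish) & fish != round(fish), "non-integral fish_lost")
  x$fish_lost <- fish

  if (!allow_duplicates) {
    key <- paste(x$country, x$unit_id, x$period_start, x$fish_lost, sep = "\r")
    flag(duplicated(key), "duplicate record")
  }

  rejected <- x[!is.na(reasons), , drop = FALSE]
  rejected$reason <- reasons[!is.na(reasons)]
  x <- x[is.na(reasons), , drop = FALSE]

  # Anchor periods: yearly -> Jan 1, monthly/submonthly -> first of month.
  yearly <- !is.na(x$resolution) & x$resolution == "yearly"
  x$period_start[yearly] <- as.Date(format(x$period_start[yearly], "%Y-01-01"))
  x$period_start[!yearly] <- as.Date(format(x$period_start[!yearly], "%Y-%m-01"))
  x$fish_lost <- as.integer(round(x$fish_lost))

  for (col in c("latitude", "longitude")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_ else x[[col]] <- as.numeric(x[[col]])
  }

  mixed <- tapply(x$resolution, x$country, function(r) length(unique(r)) > 1)
  if (any(unlist(mixed), na.rm = TRUE)) {
    warn(paste0("mixed reporting resolutions within country: ",
                paste(names(mixed)[unlist(mixed)], collapse = ", ")))
  }

  x$.row <- NULL
  out <- x[c("country", "unit_id", "period_start", "resolution", "fish_lost",
             "latitude", "longitude")]
  class(out) <- c("event_table", class(tibble::tibble()))
  attr(out, "source") <- source
  attr(out, "n_source_rows") <- n_source
  attr(out, "rejected") <- rejected
  out
}

#' Read mortality events from a CSV file
#'
#' Ingests a header-row CSV of mortality records using a column-mapping
#' schema, so datasets with arbitrary column headers can be loaded
#' without editing code. Rows failing validation are collected (with
#' row numbers and reasons) rather than silently dropped, and the
#' accepted/rejected counts are reported.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema A schema from [event_schema()] (or a named list with
#'   the same fields) mapping logical field names to column headers.
#' @param allow_duplicates Passed to [event_table()].
#' @param quiet Suppress the accepted/rejected message.
#'
#' @return An `event_table`; `attr(x, "rejected")` holds rejected rows.
#' @seealso [event_schema()], [write_events()]
#' @export
read_events <- function(path, schema = event_schema(), allow_duplicates = FALSE,
                        quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "salmonmme_io_error")
  }
  schema <- as_event_schema(schema)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- unlist(schema$columns[c("country", "unit_id", "period_start",
                                    "resolution", "fish_lost")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("schema maps to column(s) absent from ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "salmonmme_schema_error")
  }
  df <- tibble::tibble(
    country = raw[[schema$columns$country]],
    unit_id = raw[[schema$columns$unit_id]],
    period_start = as.Date(raw[[schema$columns$period_start]],
                           format = schema$date_format),
    resolution = raw[[schema$columns$resolution]],
    fish_lost = raw[[schema$columns$fish_lost]]
  )
  # keep raw string so unparseable dates are flagged, not silently NA
  bad_date <- is.na(df$period_start) & nzchar(raw[[schema$columns$period_start]])
  if (any(bad_date)) df$period_start[bad_date] <- NA
  for (col in c("latitude", "longitude")) {
    src <- schema$columns[[col]]
    if (!is.null(src) && src %in% names(raw)) {
      df[[col]] <- suppressWarnings(as.numeric(raw[[src]]))
    }
  }
  # re-inject unparseable raw dates as character for row-level rejection
  if (any(bad_date)) {
    df$period_start <- as.character(df$period_start)
    df$period_start[bad_date] <- "<unparseable>"
  }
  out <- event_table(df, allow_duplicates = allow_duplicates, source = path)
  rej <- attr(out, "rejected")
  if (!quiet) {
    inform(sprintf("read_events: %d row(s) accepted, %d rejected from %s",
                   nrow(out), nrow(rej), path))
  }
  out
}

#' Column-mapping schema for event CSV files
#'
#' Describes how the logical fields of a mortality record map onto the
#' column headers of a particular CSV file, plus the date format. The
#' mapping lives in data (and can be stored in a YAML file read with
#' [read_event_schema()]) so file layouts are an adaptation point, not
#' a code change.
#'
#' @param country,unit_id,period_start,resolution,fish_lost Column
#'   headers for the required fields.
#' @param latitude,longitude Optional column headers for coordinates.
#' @param date_format `strptime()` format for `period_start`
#'   (default ISO-8601 `"%Y-%m-%d"`).
#' @return An object of class `event_schema`.
#' @export
event_schema <- function(country = "country", unit_id = "unit_id",
                         period_start = "period_start",
                         resolution = "resolution", fish_lost = "fish_lost",
                         latitude = "latitude", longitude = "longitude",
                         date_format = "%Y-%m-%d") {
  structure(list(
    columns = list(country = country, unit_id = unit_id,
                   period_start = period_start, resolution = resolution,
                   fish_lost = fish_lost, latitude = latitude,
                   longitude = longitude),
    date_format = date_format
  ), class = "event_schema")
}

#' @rdname event_schema
#' @param path Path to a YAML file whose keys are the arguments of
#'   `event_schema()`.
#' @export
read_event_schema <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(event_schema, vals)
}

as_event_schema <- function(schema) {
  if (inherits(schema, "event_schema")) return(schema)
  if (is.list(schema)) return(do.call(event_schema, schema))
  abort("schema must be an event_schema or a named list",
        class = "salmonmme_schema_error")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d event(s), %d country(ies), source: %s\n",
              nrow(x), length(unique(x$country)), attr(x, "source")))
  NextMethod()
}

#' Total recorded mortality
#'
#' Sum of fish lost over all records in the table (the headline "how
#' many fish died" figure for a collated national or global dataset).
#'
#' @param events An `event_table`.
#' @return A numeric scalar (0 for an empty table). Numeric, not
#'   integer, because national totals overflow 32-bit integers.
#' @export
total_mortality <- function(events) {
  stopifnot(inherits(events, "event_table"))
  sum(as.numeric(events$fish_lost))
}

#' Aggregate events to a regular time series
#'
#' Collapses event records to one value per calendar period (month or
#' year) over a contiguous span: event counts, period maxima, or period
#' sums. Counting treats an empty period as a genuine zero (no extreme
#' event happened); `max` and `sum` leave empty periods missing, since
#' a maximum over no events is undefined and a fabricated zero would
#' bias trend tests.
#'
#' @param events An `event_table`, typically for a single country.
#' @param resolution `"monthly"` or `"yearly"`. Must not be finer than
#'   the records' native reporting resolution.
#' @param statistic `"count"`, `"max"`, or `"sum"`.
#' @param span Optional length-2 Date (or year number) vector giving
#'   the first and last period; defaults to the data range.
#' @return An `event_series`: a tibble with `period` (Date) and
#'   `value`, with attributes `country`, `resolution`, `statistic`.
#' @examples
#' ev <- event_table(data.frame(
#'   country = "NO", unit_id = c("a", "a", "b"),
#'   period_start = as.Date(c("2015-01-01", "2015-01-15", "2015-02-01")),
#'   resolution = "submonthly", fish_lost = c(10000L, 20000L, 5000L)
#' ))
#' aggregate_events(ev, "monthly", "max")
#' @export
aggregate_events <- function(events, resolution = c("monthly", "yearly"),
                             statistic = c("count", "max", "sum"),
                             span = NULL) {
  stopifnot(inherits(events, "event_table"))
  resolution <- match.arg(resolution)
  statistic <- match.arg(statistic)
  if (nrow(events) == 0 && is.null(span)) {
    abort("empty event table and no span given",
          class = "salmonmme_data_error")
  }
  if (resolution == "monthly" && any(events$resolution == "yearly")) {
    abort("yearly-native records cannot be aggregated at monthly resolution",
          class = "salmonmme_resolution_error")
  }

  by <- if (resolution == "monthly") "month" else "year"
  anchor <- function(d) {
    if (resolution == "monthly") as.Date(format(d, "%Y-%m-01"))
    else as.Date(format(d, "%Y-01-01"))
  }
  period <- anchor(events$period_start)
  if (is.null(span)) {
    span <- range(period)
  } else {
    if (is.numeric(span)) span <- as.Date(paste0(span, "-01-01"))
    span <- anchor(as.Date(span))
  }
  grid <- seq(span[1], span[2], by = by)
  keep <- period >= span[1] & period <= span[2]
  period <- period[keep]
  vals <- events$fish_lost[keep]

  agg <- switch(statistic,
    count = tapply(vals, factor(period, levels = as.character(grid)), length),
    max   = tapply(vals, factor(period, levels = as.character(grid)),
                   function(v) max(as.numeric(v))),
    sum   = tapply(vals, factor(period, levels = as.character(grid)),
                   function(v) sum(as.numeric(v)))
  )
  value <- as.numeric(agg)
  if (statistic == "count") value[is.na(value)] <- 0

  out <- tibble::tibble(period = grid, value = value)
  class(out) <- c("event_series", class(tibble::tibble()))
  attr(out, "country") <- if (nrow(events) > 0) unique(events$country)[1] else NA_character_
  attr(out, "resolution") <- resolution
  attr(out, "statistic") <- statistic
  out
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s %s series, %d period(s), country: %s\n",
              attr(x, "resolution"), attr(x, "statistic"), nrow(x),
              attr(x, "country")))
  NextMethod()
}

#' Site-defined MME threshold values for one country
#'
#' Holds the loss thresholds that individual companies (or counties,
#' where reporting is at county scale) use to define a mass mortality
#' event, and their arithmetic mean — the reference level that risk
#' estimates are compared against.
#'
#' @param country Country label.
#' @param values Numeric vector of positive per-unit thresholds (fish).
#' @param units Optional vector of unit labels, same length as
#'   `values`.
#' @return A `threshold_set` with elements `country`, `units`,
#'   `values`, `mean`.
#' @examples
#' mean_threshold(threshold_set("Canada", c(100000, 300000)))
#' @export
threshold_set <- function(country, values, units = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0) {
    abort("at least one threshold value is required",
          class = "salmonmme_data_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("threshold values must be positive and finite",
          class = "salmonmme_data_error")
  }
  if (is.null(units)) units <- paste0("unit_", seq_along(values))
  structure(list(country = country, units = units, values = values,
                 mean = mean(values)),
            class = "threshold_set")
}

#' @rdname threshold_set
#' @param thresholds A `threshold_set`.
#' @export
mean_threshold <- function(thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  thresholds$mean
}

#' Read per-unit MME thresholds from CSV
#'
#' Expects columns `country`, `unit`, `threshold_fish`.
#'
#' @param path CSV path.
#' @return A named list of [threshold_set()] objects, one per country.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "salmonmme_io_error")
  }
  df <- read.csv(path, check.names = FALSE)
  needed <- c("country", "unit", "threshold_fish")
  if (!all(needed %in% names(df))) {
    abort("thresholds CSV needs columns country, unit, threshold_fish",
          class = "salmonmme_schema_error")
  }
  out <- lapply(split(df, df$country), function(d) {
    threshold_set(d$country[1], d$threshold_fish, units = d$unit)
  })
  out
}
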