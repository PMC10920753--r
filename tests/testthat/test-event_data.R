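test_that("read_events ingests a valid fixture and reports provenance", {
  path <- write_events_csv(data.frame(
    country = "Testland", unit_id = "site-1",
    period_start = c("2015-01-01", "2015-01-15", "2015-02-01"),
    resolution = "submonthly", fish_lost = c(10, 20, 30)
  ))
  ev <- read_events(path, quiet = TRUE)
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 3)
  expect_equal(attr(ev, "n_source_rows"), 3)
  expect_equal(attr(ev, "source"), path)
  expect_equal(total_mortality(ev), 60)
})

test_that("header-only CSV yields an empty table; missing file errors", {
  path <- tempfile(fileext = ".csv")
  writeLines("country,unit_id,period_start,resolution,fish_lost", path)
  ev <- read_events(path, quiet = TRUE)
  expect_equal(nrow(ev), 0)
  expect_equal(total_mortality(ev), 0)
  expect_error(read_events(tempfile()), class = "salmonmme_io_error")
})

test_that("schema mapping adapts to foreign column layouts", {
  path <- write_events_csv(data.frame(
    nation = "Testland", farm = "f1", dato = "01/03/2016",
    res = "monthly", dode_fisk = 1234
  ))
  sch <- event_schema(country = "nation", unit_id = "farm",
                      period_start = "dato", resolution = "res",
                      fish_lost = "dode_fisk", date_format = "%d/%m/%Y")
  ev <- read_events(path, schema = sch, quiet = TRUE)
  expect_equal(ev$period_start, as.Date("2016-03-01"))
  expect_equal(ev$fish_lost, 1234L)
  # missing mapped column is a schema error, not a row error
  expect_error(read_events(path, quiet = TRUE),
               class = "salmonmme_schema_error")
})

test_that("invalid rows are collected with reasons, never silently dropped", {
  path <- write_events_csv(data.frame(
    country = "Testland", unit_id = "s",
    period_start = c("2015-01-01", "not-a-date", "2015-03-01", "2015-04-01"),
    resolution = c("monthly", "monthly", "monthly", "monthly"),
    fish_lost = c(10, 10, -5, 2.5)
  ))
  ev <- read_events(path, quiet = TRUE)
  rej <- attr(ev, "rejected")
  expect_equal(nrow(ev), 1)
  expect_equal(nrow(rej), 3)
  expect_setequal(rej$reason, c("unparseable period_start",
                                "negative fish_lost",
                                "non-integral fish_lost"))
})

test_that("duplicates are rejected by default and kept on request", {
  df <- data.frame(country = "Testland", unit_id = "s",
                   period_start = "2015-01-01", resolution = "monthly",
                   fish_lost = c(100, 100))
  ev <- event_table(df)
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "rejected")$reason, "duplicate record")
  expect_equal(nrow(event_table(df, allow_duplicates = TRUE)), 2)
})

test_that("aggregation matches hand-enumerated monthly max and count", {
  ev <- make_events(fish = c(10000L, 20000L, 5000L),
                    dates = as.Date(c("2015-01-05", "2015-01-20", "2015-02-10")),
                    unit = c("a", "b", "a"))
  mx <- aggregate_events(ev, "monthly", "max")
  expect_equal(mx$value, c(20000, 5000))
  expect_equal(mx$period, as.Date(c("2015-01-01", "2015-02-01")))
  ct <- aggregate_events(ev, "monthly", "count")
  expect_equal(ct$value, c(2, 1))
  one <- aggregate_events(make_events(fish = 7L), "monthly", "max")
  expect_equal(one$value, 7)
  expect_equal(nrow(one), 1)
})

test_that("empty periods are zero for counts but missing for maxima", {
  ev <- make_events(fish = c(1L, 2L),
                    dates = as.Date(c("2015-01-01", "2015-04-01")))
  ct <- aggregate_events(ev, "monthly", "count")
  expect_equal(ct$value, c(1, 0, 0, 1))
  mx <- aggregate_events(ev, "monthly", "max")
  expect_equal(mx$value, c(1, NA, NA, 2))
})

test_that("yearly-native records refuse monthly aggregation", {
  ev <- make_events(fish = c(5L, 6L), resolution = "yearly",
                    dates = as.Date(c("2015-01-01", "2016-01-01")))
  expect_error(aggregate_events(ev, "monthly", "count"),
               class = "salmonmme_resolution_error")
  expect_equal(aggregate_events(ev, "yearly", "sum")$value, c(5, 6))
})

test_that("aggregated sums conserve total mortality and counts sum to N", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:60, 1)
    ev <- make_events(
      fish = sample.int(1e5, n, replace = TRUE),
      dates = as.Date("2014-01-01") + sample.int(1500, n, replace = TRUE)
    )
    sm <- aggregate_events(ev, "monthly", "sum")
    expect_equal(sum(sm$value, na.rm = TRUE), total_mortality(ev))
    ct <- aggregate_events(ev, "monthly", "count")
    expect_true(all(ct$value >= 0 & ct$value == round(ct$value)))
    expect_equal(sum(ct$value), nrow(ev))
  }
})

test_that("write/read round-trips an event table", {
  ev <- make_events(fish = c(10L, 20L, 30L))
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path, quiet = TRUE)
  expect_equal(as.data.frame(back)[1:5], as.data.frame(ev)[1:5])
})

test_that("threshold sets validate and average correctly", {
  expect_equal(mean_threshold(threshold_set("X", c(100000, 300000))), 200000)
  expect_equal(mean_threshold(threshold_set("X", 250000)), 250000)
  vals <- c(120000, 90000, 310000, 45000, 205000)
  expect_equal(mean_threshold(threshold_set("X", vals)),
               (120000 + 90000 + 310000 + 45000 + 205000) / 5)
  expect_error(threshold_set("X", numeric(0)), class = "salmonmme_data_error")
  expect_error(threshold_set("X", c(10, -1)), class = "salmonmme_data_error")
})

test_that("threshold CSV reader builds one set per country", {
  path <- system.file("extdata", "synthetic_thresholds.csv",
                      package = "salmonmme")
  thr <- read_thresholds(path)
  expect_named(thr, c("Norlandia", "Yearvia"))
  expect_equal(mean_threshold(thr$Norlandia), mean(c(150000, 250000, 200000)))
})

test_that("GeoJSON export writes one point feature per located event", {
  ev <- make_events(fish = c(1L, 2L, 3L))
  ev$latitude <- c(60.1, NA, 61.2)
  ev$longitude <- c(5.5, 6.0, NA)
  path <- tempfile(fileext = ".geojson")
  expect_message(export_geojson(ev, path), "skipping 2")
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1)
  expect_equal(gj$features[[1]]$properties$fish_lost, 1)
})
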