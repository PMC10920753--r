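# Shared fixture builders. Everything is constructed in code so the
# repository carries no binary data.

make_events <- function(fish = c(10L, 20L, 30L),
                        dates = as.Date("2015-01-01") + seq_along(fish) - 1,
                        country = "Testland", unit = "site-1",
                        resolution = "submonthly", ...) {
  event_table(data.frame(
    country = country, unit_id = unit, period_start = dates,
    resolution = resolution, fish_lost = fish
  ), ...)
}

write_events_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# independent brute-force Mann-Kendall oracle: explicit double loop for
# S, explicit tie-group scan for Var(S), base-R Kendall tau
mk_oracle <- function(x) {
  n <- length(x)
  S <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  }
  tg <- as.numeric(table(x))
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tg * (tg - 1) * (2 * tg + 5))) / 18
  tau <- suppressWarnings(cor(x, seq_len(n), method = "kendall"))
  list(S = S, var_S = var_S, tau = tau)
}
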