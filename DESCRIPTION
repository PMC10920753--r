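Package: salmonmme
Title: Trend and Extreme-Value Analysis of Mass Mortality Events in
    Salmon Aquaculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of mass mortality events
    (MMEs) in farmed-salmon production: ingestion and validation of
    country-level mortality-event records, aggregation to monthly or
    yearly series, detection of monotonic trends in the frequency and
    magnitude of the largest loss events (Mann-Kendall test with tie
    correction and autocorrelation-averaging adjustment, lowess
    visual smoothing), and peaks-over-threshold extreme-value
    estimation of maximum potential loss per country (generalized
    Pareto maximum likelihood, Value-at-Risk and Expected Shortfall
    with return-level bounds, comparison against site-defined MME
    thresholds). Includes a synthetic event-stream generator with
    controlled trend, heavy-tailed magnitudes, seasonality and lag-1
    autocorrelation so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
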