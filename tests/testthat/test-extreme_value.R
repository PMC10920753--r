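test_that("POT threshold selection follows the order-statistic convention", {
  pot <- select_pot_threshold(1:100, 0.10)
  expect_equal(pot$u, as.numeric(quantile(1:100, 0.90, type = 7)))
  expect_equal(pot$n_exceed, 10)
  expect_equal(pot$exceedances, 91:100 - pot$u)

  med <- select_pot_threshold(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 0.5)
  expect_equal(med$u, 5.5)

  expect_error(select_pot_threshold(rep(7, 50), 0.10),
               class = "salmonmme_data_error")
  expect_error(select_pot_threshold(1:5, 0.10),
               class = "salmonmme_data_error")
  expect_error(select_pot_threshold(1:100, 1.5),
               class = "salmonmme_parameter_error")
})

test_that("GPD maximum likelihood recovers known parameters", {
  y <- generate_gpd_sample(xi = 0.2, sigma = 1, n = 10000, seed = 101)
  fit <- fit_gpd(y)
  expect_lt(abs(fit$xi - 0.2), 0.05)
  expect_lt(abs(fit$sigma - 1), 0.05)
  expect_false(isTRUE(fit$convergence$boundary))

  expo <- generate_gpd_sample(xi = 0, sigma = 1, n = 10000, seed = 102)
  expect_lt(abs(fit_gpd(expo)$xi), 0.05)
})

test_that("the fitted likelihood dominates the truth on the same sample", {
  for (s in 1:5) {
    y <- generate_gpd_sample(xi = 0.3, sigma = 2, n = 500, seed = 200 + s)
    fit <- fit_gpd(y)
    expect_gte(fit$log_likelihood, gpd_loglik(0.3, 2, y) - 1e-6)
  }
})

test_that("fit validity and bookkeeping invariants hold", {
  y <- generate_gpd_sample(xi = -0.3, sigma = 5, n = 2000, seed = 300)
  fit <- fit_gpd(y, u = 10, n = 20000)
  expect_gt(fit$sigma, 0)
  expect_lte(fit$n_exceed, fit$n)
  expect_true(all(1 + fit$xi * y / fit$sigma > 0))
  expect_error(fit_gpd(c(1, 2, 3)), class = "salmonmme_data_error")
  expect_error(fit_gpd(c(-1, 1, 2, 3, 4, 5)), class = "salmonmme_data_error")
})

test_that("VaR and ES reproduce hand-derived closed forms", {
  f <- gpd_fit(u = 0, xi = 0.5, sigma = 1, n = 10, n_exceed = 1)
  expect_equal(value_at_risk(f, 0.999), 18, tolerance = 1e-9)
  expect_equal(expected_shortfall(f, 0.999), 38, tolerance = 1e-9)

  e <- gpd_fit(u = 0, xi = 0, sigma = 1, n = 1, n_exceed = 1)
  expect_equal(value_at_risk(e, 0.999), -log(0.001))
  # exponential memorylessness: ES = VaR + sigma
  expect_equal(expected_shortfall(e, 0.999), -log(0.001) + 1)

  expect_error(value_at_risk(f, 1.2), class = "salmonmme_parameter_error")
  expect_error(value_at_risk(f, 0.05), class = "salmonmme_domain_error")
  inf <- gpd_fit(u = 0, xi = 1.1, sigma = 1, n = 10, n_exceed = 5)
  expect_error(expected_shortfall(inf, 0.999),
               class = "salmonmme_domain_error")
})

test_that("VaR increases in q and ES dominates VaR for xi in [0, 1)", {
  qs <- c(0.95, 0.99, 0.999, 0.9999)
  for (xi in c(0, 0.2, 0.5, 0.9)) {
    f <- gpd_fit(u = 100, xi = xi, sigma = 50, n = 10, n_exceed = 5)
    v <- vapply(qs, value_at_risk, numeric(1), fit = f)
    expect_true(all(diff(v) > 0))
    expect_true(all(vapply(qs, expected_shortfall, numeric(1), fit = f) >= v))
    expect_true(all(v >= 100))
  }
})

test_that("the general formulas meet the exponential limit as xi -> 0", {
  f0 <- gpd_fit(u = 2, xi = 0, sigma = 3, n = 10, n_exceed = 5)
  fe <- gpd_fit(u = 2, xi = 1e-8, sigma = 3, n = 10, n_exceed = 5)
  expect_equal(value_at_risk(fe, 0.999), value_at_risk(f0, 0.999),
               tolerance = 1e-6)
  expect_equal(expected_shortfall(fe, 0.999), expected_shortfall(f0, 0.999),
               tolerance = 1e-6)
  expect_equal(qgpd(0.9, 1e-8, 1), qgpd(0.9, 0, 1), tolerance = 1e-6)
})

test_that("VaR and ES agree with Monte-Carlo tail oracles", {
  x <- generate_gpd_sample(xi = 0.2, sigma = 1, n = 1e5, seed = 404)
  fit <- gpd_fit(u = 0, xi = 0.2, sigma = 1, n = length(x),
                 n_exceed = length(x))
  v99 <- value_at_risk(fit, 0.99)
  expect_equal(v99, as.numeric(quantile(x, 0.99, type = 7)),
               tolerance = 0.05)
  es99 <- expected_shortfall(fit, 0.99)
  expect_equal(es99, mean(x[x > v99]), tolerance = 0.05)
})

test_that("fitted survival matches empirical tail frequencies (PP check)", {
  y <- generate_gpd_sample(xi = 0.4, sigma = 2, n = 1000, seed = 505)
  fit <- fit_gpd(y)
  p_emp <- (seq_along(y) - 0.5) / length(y)
  p_fit <- pgpd(sort(y), xi = fit$xi, sigma = fit$sigma)
  expect_gt(cor(p_emp, p_fit), 0.99)
})

test_that("ES error from the full chain shrinks as the tail sample grows", {
  grid <- c(-0.2, 0, 0.2, 0.5)
  err_at <- function(n) {
    mean(vapply(seq_along(grid), function(i) {
      xi <- grid[i]
      y <- generate_gpd_sample(xi = xi, sigma = 1, n = n, seed = 600 + i)
      fit <- fit_gpd(y)
      es <- expected_shortfall(fit, 0.999)
      f_true <- gpd_fit(u = 0, xi = xi, sigma = 1, n = n, n_exceed = n)
      abs(es / expected_shortfall(f_true, 0.999) - 1)
    }, numeric(1)))
  }
  expect_lt(err_at(5000), err_at(200))
})

test_that("country risk summary recovers an analytic synthetic tail", {
  m <- magnitude_gpd_tail(body_scale = 1e5, shape = 0.2, scale = 5e4,
                          tail_fraction = 0.1)
  cfg <- generator_config(base_rate = 30, magnitude = m, seed = 808)
  ev <- generate_events(cfg)
  est <- country_risk_summary(ev, basis = "per_event", top_fraction = 0.10)
  truth <- analytic_tail_risk(m, q = 0.999)
  expect_lt(abs(est$es_point / truth$es - 1), 0.25)
  expect_gte(est$var_upper, est$var_lower)
  expect_gte(est$es_point, est$var_lower)
  expect_gte(est$var_lower, est$fit$u)
})

test_that("risk summary respects basis and attaches threshold comparison", {
  set.seed(77)
  ev <- make_events(fish = as.integer(round(exp(rnorm(60, 10, 1)))),
                    dates = rep(as.Date("2012-01-01") + (0:9) * 370, 6),
                    resolution = "yearly")
  thr <- threshold_set("Testland", c(2e5, 4e5))
  est <- country_risk_summary(ev, thresholds = thr, basis = "per_year",
                              top_fraction = 0.5)
  expect_equal(est$threshold_mean, 3e5)
  expect_equal(est$exceedance_ratio, est$es_point / 3e5)
  expect_equal(est$fit$n, 10)  # yearly sums, not per-event losses
  row <- as_risk_row(est)
  expect_equal(nrow(row), 1)
  expect_named(row, c("country", "basis", "q", "top_fraction", "u", "xi",
                      "sigma", "n", "n_exceed", "var_lower", "var_upper",
                      "es_point", "threshold_mean", "exceedance_ratio"))
})
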