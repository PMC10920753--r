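# Peaks-over-threshold extreme-value analysis: empirical threshold
# selection, GPD maximum likelihood, Value-at-Risk / Expected Shortfall,
# and the per-country risk summary compared against MME thresholds.

#' Select a peaks-over-threshold threshold empirically
#'
#' Sets the POT threshold `u` at the empirical `1 - top_fraction`
#' quantile of the loss sample (type-7 order-statistic interpolation),
#' with exceedances defined strictly above `u`. With `top_fraction`
#' 0.10 this isolates the top 10% of events — the same device used for
#' frequency tracking — so the tail model and the trend analysis treat
#' "an MME" consistently.
#'
#' @param magnitudes Numeric loss sample, length `>= 10`.
#' @param top_fraction Proportion in (0, 1).
#' @return A list with `u` (threshold), `exceedances` (values above
#'   `u`, minus `u`), `n` (sample size) and `n_exceed`.
#' @export
select_pot_threshold <- function(magnitudes, top_fraction) {
  magnitudes <- as.numeric(magnitudes)
  magnitudes <- magnitudes[!is.na(magnitudes)]
  if (length(magnitudes) < 10) {
    abort("need at least 10 observations to select a threshold",
          class = "salmonmme_data_error")
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("top_fraction must lie in (0, 1)",
          class = "salmonmme_parameter_error")
  }
  u <- as.numeric(quantile(magnitudes, 1 - top_fraction, type = 7))
  exceed <- magnitudes[magnitudes > u] - u
  if (length(exceed) < 5) {
    abort(sprintf("only %d exceedance(s) above u = %g; need >= 5 to fit",
                  length(exceed), u),
          class = "salmonmme_data_error")
  }
  list(u = u, exceedances = exceed, n = length(magnitudes),
       n_exceed = length(exceed))
}

#' Construct a GPD fit object
#'
#' Bundles a POT threshold with GPD parameters and sample bookkeeping.
#' Usually produced by [fit_gpd()]; the constructor is exported so that
#' closed-form risk formulas can be evaluated at known parameters.
#'
#' @param u Threshold (fish).
#' @param xi Shape.
#' @param sigma Scale, `> 0`.
#' @param n Total observations behind the threshold choice.
#' @param n_exceed Number of exceedances above `u`.
#' @param log_likelihood Maximized GPD log-likelihood (NA when the
#'   object holds assumed rather than fitted parameters).
#' @param convergence List of optimizer diagnostics.
#' @return A `gpd_fit`.
#' @export
gpd_fit <- function(u, xi, sigma, n, n_exceed, log_likelihood = NA_real_,
                    convergence = list()) {
  .gpd_check(sigma)
  if (n_exceed > n) {
    abort("n_exceed cannot exceed n", class = "salmonmme_parameter_error")
  }
  structure(list(u = u, xi = xi, sigma = sigma, n = n, n_exceed = n_exceed,
                 log_likelihood = log_likelihood, convergence = convergence),
            class = "gpd_fit")
}

#' @export
print.gpd_fit <- function(x, ...) {
  cat("Generalized Pareto fit (peaks over threshold)\n")
  cat(sprintf("  u = %g  xi = %.4f  sigma = %.4g\n", x$u, x$xi, x$sigma))
  cat(sprintf("  n = %d, exceedances = %d, logLik = %.3f\n",
              x$n, x$n_exceed, x$log_likelihood))
  if (isTRUE(x$convergence$boundary)) {
    cat("  warning: shape estimate at the search boundary\n")
  }
  invisible(x)
}

# negative GPD log-likelihood on (xi, log sigma); a large finite
# penalty outside the support keeps L-BFGS-B line searches finite
.gpd_nll <- function(par, y) {
  xi <- par[1]; sigma <- exp(par[2])
  m <- length(y)
  if (abs(xi) < 1e-9) {
    return(m * log(sigma) + sum(y) / sigma)
  }
  z <- 1 + xi * y / sigma
  if (any(z <= 0)) return(1e10)
  m * log(sigma) + (1 + 1 / xi) * sum(log(z))
}

#' GPD log-likelihood of exceedances
#'
#' \eqn{\ell(\xi,\sigma) = -m\log\sigma - (1 + 1/\xi)\sum_i
#' \log(1 + \xi y_i / \sigma)}, with the exponential limit at
#' \eqn{\xi = 0}.
#'
#' @param xi,sigma GPD parameters (`sigma > 0`).
#' @param y Positive exceedances (already shifted by the threshold).
#' @return Log-likelihood (scalar; `-Inf` outside the support).
#' @export
gpd_loglik <- function(xi, sigma, y) {
  .gpd_check(sigma)
  nll <- .gpd_nll(c(xi, log(sigma)), as.numeric(y))
  if (nll >= 1e10) return(-Inf)
  -nll
}

# probability-weighted-moments start (Hosking & Wallis)
.gpd_pwm_start <- function(y) {
  y <- sort(y)
  m <- length(y)
  b0 <- mean(y)
  b1 <- sum((seq_len(m) - 1) / (m - 1) * y) / m
  denom <- b0 - 2 * b1
  if (!is.finite(denom) || denom == 0) return(c(0.1, log(b0)))
  k <- b0 / denom - 2          # Hosking's k; our xi = -k
  sigma <- 2 * b0 * b1 / denom
  xi <- -k
  if (!is.finite(sigma) || sigma <= 0) sigma <- b0
  c(max(min(xi, 0.9), -0.85), log(sigma))
}

#' Fit a generalized Pareto distribution to exceedances
#'
#' Maximum-likelihood estimation of the GPD shape and scale on the
#' exceedances above a POT threshold, by bounded quasi-Newton search on
#' `(xi, log sigma)` from five starting points (a probability-weighted-
#' moments start plus perturbations), keeping the best-likelihood
#' convergent solution. The shape search box is `[-0.9, 0.95]`; a
#' solution at the box edge is flagged.
#'
#' @param exceedances Positive numeric exceedances (length `>= 5`), or
#'   a list from [select_pot_threshold()] (threshold bookkeeping then
#'   carries through).
#' @param u,n Threshold and total sample size to record when raw
#'   exceedances are supplied (defaults 0 and `length(exceedances)`).
#' @return A [gpd_fit()] with `log_likelihood` and convergence
#'   diagnostics (`iterations`, `convergence` code, `boundary` flag,
#'   `n_starts_converged`).
#' @examples
#' y <- generate_gpd_sample(xi = 0.2, sigma = 1, n = 2000, seed = 7)
#' fit_gpd(y)
#' @export
fit_gpd <- function(exceedances, u = 0, n = NULL) {
  if (is.list(exceedances) && !is.null(exceedances$exceedances)) {
    pot <- exceedances
    y <- pot$exceedances; u <- pot$u; n <- pot$n
  } else {
    y <- as.numeric(exceedances)
    if (is.null(n)) n <- length(y)
  }
  y <- y[!is.na(y)]
  if (length(y) < 5) {
    abort("need at least 5 exceedances to fit a GPD",
          class = "salmonmme_data_error")
  }
  if (any(y <= 0)) {
    abort("exceedances must be strictly positive",
          class = "salmonmme_data_error")
  }

  lower <- c(-0.9, -Inf); upper <- c(0.95, Inf)
  start0 <- .gpd_pwm_start(y)
  starts <- list(
    start0,
    start0 + c(0.2, 0),
    start0 + c(-0.2, 0),
    start0 + c(0, 0.5),
    c(0.1, log(mean(y)))
  )
  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    s[1] <- max(min(s[1], upper[1]), lower[1])
    fit <- tryCatch(
      optim(s, .gpd_nll, y = y, method = "L-BFGS-B",
            lower = lower, upper = c(upper[1], 50),
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      # derivative-free fallback; box enforced by penalty
      fit <- tryCatch(
        optim(s, function(p) {
          if (p[1] < lower[1] || p[1] > upper[1]) return(1e10)
          .gpd_nll(p, y)
        }, method = "Nelder-Mead", control = list(maxit = 1000)),
        error = function(e) NULL
      )
    }
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || n_conv == 0) {
    abort("GPD fit failed to converge from all starting points",
          class = "salmonmme_fit_error")
  }
  xi <- best$par[1]; sigma <- exp(best$par[2])
  boundary <- xi <= lower[1] + 1e-6 || xi >= upper[1] - 1e-6
  gpd_fit(u = u, xi = xi, sigma = sigma, n = n, n_exceed = length(y),
          log_likelihood = -best$value,
          convergence = list(code = best$convergence,
                             iterations = best$counts[["function"]],
                             boundary = boundary,
                             n_starts_converged = n_conv))
}

#' Value-at-Risk from a POT/GPD fit
#'
#' The loss level not exceeded with probability `q` under the fitted
#' tail model:
#' \eqn{VaR_q = u + (\sigma/\xi)\{[(n/n_u)(1-q)]^{-\xi} - 1\}} with the
#' \eqn{\xi = 0} limit \eqn{u - \sigma\log[(n/n_u)(1-q)]}, where
#' `n/n_u` converts the tail probability to an exceedance probability
#' above `u`. A "1/1000 event" is `q = 0.999`.
#'
#' @param fit A `gpd_fit`.
#' @param q Confidence level in (0, 1); must exceed the empirical
#'   coverage of the threshold (`1 - n_exceed/n`), otherwise the
#'   requested quantile lies below `u` and outside the tail model.
#' @return Estimated loss (fish).
#' @examples
#' f <- gpd_fit(u = 0, xi = 0.5, sigma = 1, n = 10, n_exceed = 1)
#' value_at_risk(f, 0.999)  # 18
#' @export
value_at_risk <- function(fit, q) {
  stopifnot(inherits(fit, "gpd_fit"))
  if (q <= 0 || q >= 1) {
    abort("q must lie in (0, 1)", class = "salmonmme_parameter_error")
  }
  ratio <- fit$n / fit$n_exceed
  if (q <= 1 - fit$n_exceed / fit$n) {
    abort("q does not exceed the threshold's empirical coverage; VaR would fall below u",
          class = "salmonmme_domain_error")
  }
  a <- ratio * (1 - q)
  if (abs(fit$xi) < 1e-9) {
    fit$u - fit$sigma * log(a)
  } else {
    fit$u + (fit$sigma / fit$xi) * (a^(-fit$xi) - 1)
  }
}

#' Expected Shortfall from a POT/GPD fit
#'
#' Expected loss given that the loss exceeds \eqn{VaR_q} (conditional
#' VaR): \eqn{ES_q = VaR_q/(1-\xi) + (\sigma - \xi u)/(1-\xi)}, the
#' "expected loss within the worst \eqn{1-q} of cases". Requires
#' \eqn{\xi < 1}; beyond that the conditional mean is infinite and an
#' error is raised rather than a clipped value returned.
#'
#' @inheritParams value_at_risk
#' @return Estimated expected loss (fish).
#' @examples
#' f <- gpd_fit(u = 0, xi = 0.5, sigma = 1, n = 10, n_exceed = 1)
#' expected_shortfall(f, 0.999)  # 38
#' @export
expected_shortfall <- function(fit, q) {
  stopifnot(inherits(fit, "gpd_fit"))
  if (fit$xi >= 1) {
    abort(sprintf("xi = %.3f >= 1: the conditional tail mean is infinite",
                  fit$xi),
          class = "salmonmme_domain_error")
  }
  v <- value_at_risk(fit, q)
  v / (1 - fit$xi) + (fit$sigma - fit$xi * fit$u) / (1 - fit$xi)
}

#' Per-country maximum-loss summary
#'
#' The full extreme-value chain for one country: assemble loss
#' magnitudes (per-event losses for sub-yearly reporters, yearly
#' aggregate losses for yearly reporters), select the POT threshold at
#' the country's top fraction, fit the GPD, and report Expected
#' Shortfall at `q` as the point estimate of the maximum potential
#' loss, bounded by the 1/1000-event VaR (`q`) below and the
#' 1/10,000-event VaR (`1 - (1-q)/10`) above. When a threshold set is
#' supplied, the estimate is compared to the mean site-defined MME
#' threshold via `exceedance_ratio`.
#'
#' @param events An `event_table` for a single country.
#' @param thresholds Optional [threshold_set()] for the country.
#' @param basis `"per_event"` (sub-yearly reporters) or `"per_year"`
#'   (yearly reporters: magnitudes are yearly summed losses).
#' @param top_fraction POT fraction (0.10 for sub-yearly reporters,
#'   0.50 where yearly reporting leaves few records).
#' @param q Confidence level (default 0.999, the worst 0.1% of cases).
#' @return A `risk_estimate`: list with the country, basis, fit, and
#'   `es_point`, `var_lower`, `var_upper`, `threshold_mean`,
#'   `exceedance_ratio`.
#' @export
country_risk_summary <- function(events, thresholds = NULL,
                                 basis = c("per_event", "per_year"),
                                 top_fraction = 0.10, q = 0.999) {
  stopifnot(inherits(events, "event_table"))
  basis <- match.arg(basis)
  if (nrow(events) == 0) {
    abort("no events for risk summary", class = "salmonmme_data_error")
  }
  country <- unique(events$country)
  if (length(country) > 1) {
    abort("risk summary is per-country; got multiple countries",
          class = "salmonmme_data_error")
  }
  magnitudes <- if (basis == "per_event") {
    as.numeric(events$fish_lost)
  } else {
    yearly <- aggregate_events(events, "yearly", "sum")
    yearly$value[!is.na(yearly$value)]
  }
  res <- tryCatch({
    pot <- select_pot_threshold(magnitudes, top_fraction)
    fit <- fit_gpd(pot)
    q_upper <- 1 - (1 - q) / 10
    list(fit = fit,
         es_point = expected_shortfall(fit, q),
         var_lower = value_at_risk(fit, q),
         var_upper = value_at_risk(fit, q_upper))
  }, error = function(e) {
    abort(paste0("risk summary failed for ", country, ": ",
                 conditionMessage(e)),
          class = "salmonmme_fit_error", parent = e)
  })
  thr_mean <- if (!is.null(thresholds)) mean_threshold(thresholds) else NA_real_
  out <- list(country = country, basis = basis, q = q,
              top_fraction = top_fraction, fit = res$fit,
              es_point = res$es_point, var_lower = res$var_lower,
              var_upper = res$var_upper, threshold_mean = thr_mean,
              exceedance_ratio = res$es_point / thr_mean)
  class(out) <- "risk_estimate"
  out
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("Maximum-loss estimate for %s (%s basis)\n",
              x$country, x$basis))
  cat(sprintf("  ES at q = %.4g: %s fish\n", x$q,
              format(round(x$es_point), big.mark = ",")))
  cat(sprintf("  bounds: 1/%d event %s  --  1/%d event %s fish\n",
              round(1 / (1 - x$q)), format(round(x$var_lower), big.mark = ","),
              round(10 / (1 - x$q)), format(round(x$var_upper), big.mark = ",")))
  if (!is.na(x$threshold_mean)) {
    cat(sprintf("  mean MME threshold: %s fish (exceedance ratio %.1f)\n",
                format(round(x$threshold_mean), big.mark = ","),
                x$exceedance_ratio))
  }
  invisible(x)
}

#' Flatten a risk estimate to one report row
#'
#' @param x A `risk_estimate`.
#' @return A one-row tibble with country, basis, threshold and fit
#'   parameters, VaR/ES estimates and threshold comparison.
#' @export
as_risk_row <- function(x) {
  stopifnot(inherits(x, "risk_estimate"))
  tibble::tibble(
    country = x$country, basis = x$basis, q = x$q,
    top_fraction = x$top_fraction,
    u = x$fit$u, xi = x$fit$xi, sigma = x$fit$sigma,
    n = x$fit$n, n_exceed = x$fit$n_exceed,
    var_lower = x$var_lower, var_upper = x$var_upper,
    es_point = x$es_point, threshold_mean = x$threshold_mean,
    exceedance_ratio = x$exceedance_ratio
  )
}
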