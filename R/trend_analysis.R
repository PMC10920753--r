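# Trend detection: top-fraction event selection, Mann-Kendall test with
# tie correction and continuity correction, autocorrelation diagnosis
# with block-averaging adjustment, and lowess smoothing for display.

#' Select a country's largest loss events
#'
#' Keeps the `k = ceiling(fraction * N)` events with the largest fish
#' loss within one country — the device used to track "the most severe
#' loss events" while staying agnostic to jurisdiction-specific MME
#' definitions (top 10% for sub-yearly reporters; top 50% where yearly
#' reporting leaves too few records). Ties at the cutoff are broken by
#' earlier `period_start`, then lexicographic `unit_id`, so selection
#' is deterministic.
#'
#' @param events An `event_table` from a single country.
#' @param fraction Proportion in (0, 1].
#' @return An `event_table` with the selected events (original order of
#'   magnitude rank).
#' @export
select_top_fraction <- function(events, fraction) {
  stopifnot(inherits(events, "event_table"))
  if (nrow(events) == 0) {
    abort("cannot select from an empty event table",
          class = "salmonmme_data_error")
  }
  if (length(unique(events$country)) > 1) {
    abort("top-fraction selection is within-country only",
          class = "salmonmme_data_error")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]", class = "salmonmme_parameter_error")
  }
  k <- ceiling(fraction * nrow(events))
  ord <- order(-events$fish_lost, events$period_start, events$unit_id)
  out <- events[ord[seq_len(k)], , drop = FALSE]
  class(out) <- class(events)
  attr(out, "source") <- attr(events, "source")
  out
}

#' Mann-Kendall test for a monotonic trend
#'
#' Nonparametric trend test based on the sign concordance of all
#' observation pairs: \eqn{S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)},
#' with the tie-corrected variance
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)]/18}
#' over tie groups of size \eqn{t_g}, a \eqn{\pm 1} continuity
#' correction in the normal deviate \eqn{Z}, Kendall's tau-b (ties in
#' values corrected; the time index is assumed untied), and a
#' two-tailed normal p-value. Missing values are removed first (they
#' arise from empty periods in maxima series).
#'
#' @param x Numeric vector or an `event_series`; `n >= 3` after
#'   removing `NA`.
#' @return An `mk_trend` with elements `S`, `var_S`, `Z`, `tau`, `p`,
#'   `n`, and `adjustment` (averaging trail; window 1 when run
#'   directly).
#' @examples
#' mann_kendall(c(3, 1, 2, 4))   # S = 2, tau = 1/3
#' @export
mann_kendall <- function(x) {
  if (inherits(x, "event_series")) x <- x$value
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) {
    abort("need at least 3 non-missing values for a trend test",
          class = "salmonmme_data_error")
  }
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))  # [i < j] pairs: d[j, i] = x_j - x_i

  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18

  D <- n * (n - 1) / 2
  Tt <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((D - Tt) * D)

  if (var_S <= 0 || denom == 0) {   # all values equal
    res <- list(S = as.integer(S), var_S = 0, Z = 0, tau = 0, p = 1, n = n,
                adjustment = list(window = 1L, n_original = n, rounds = 0L))
    class(res) <- "mk_trend"
    return(res)
  }

  Z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  tau <- S / denom
  p <- 2 * pnorm(-abs(Z))
  res <- list(S = as.integer(S), var_S = var_S, Z = Z, tau = tau, p = p, n = n,
              adjustment = list(window = 1L, n_original = n, rounds = 0L))
  class(res) <- "mk_trend"
  res
}

#' @export
print.mk_trend <- function(x, ...) {
  cat("Mann-Kendall trend test\n")
  cat(sprintf("  n = %d  S = %d  Var(S) = %.3f\n", x$n, x$S, x$var_S))
  cat(sprintf("  Z = %.4f  tau = %.4f  p = %.4g (two-tailed)\n",
              x$Z, x$tau, x$p))
  if (x$adjustment$window > 1) {
    cat(sprintf("  autocorrelation adjustment: window %d (from n = %d)\n",
                x$adjustment$window, x$adjustment$n_original))
  }
  invisible(x)
}

#' Diagnose serial autocorrelation
#'
#' Sample autocorrelations at lags `1..max_lag`, each flagged
#' significant when `|r_k|` exceeds the large-sample two-sided bound
#' \eqn{z_{1-\alpha/2}/\sqrt{n}}. The recommended averaging window is
#' 1 + the largest contiguous significant lag starting at lag 1 (window
#' 1 when lag 1 is not significant) — the window over which the series
#' should be block-averaged before a trend test that assumes
#' independence.
#'
#' @param x Numeric vector or `event_series` (NA removed); must be
#'   non-constant with `n >= max_lag + 3`.
#' @param max_lag Largest lag examined (default 12, one year of monthly
#'   data).
#' @param alpha Two-sided significance level for the bound.
#' @return An `autocorr_result`: tibble of `lag`, `r`, `significant`,
#'   plus attributes `window` and `bound`.
#' @export
autocorrelation_diagnose <- function(x, max_lag = 12, alpha = 0.05) {
  if (inherits(x, "event_series")) x <- x$value
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  max_lag <- min(max_lag, n - 3)
  if (n < 4 || max_lag < 1) {
    abort("series too short to diagnose autocorrelation",
          class = "salmonmme_data_error")
  }
  if (sd(x) == 0) {
    abort("autocorrelation is undefined for a constant series",
          class = "salmonmme_data_error")
  }
  r <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)[-1]
  bound <- qnorm(1 - alpha / 2) / sqrt(n)
  sig <- abs(r) > bound
  window <- 1L
  while (window <= length(sig) && sig[window]) window <- window + 1L
  out <- tibble::tibble(lag = seq_along(r), r = r, significant = sig)
  class(out) <- c("autocorr_result", class(tibble::tibble()))
  attr(out, "window") <- window
  attr(out, "bound") <- bound
  attr(out, "n") <- n
  out
}

#' Block-average a series
#'
#' Replaces non-overlapping consecutive blocks of `window` values by
#' their mean (a trailing partial block is averaged over its actual
#' length), shortening the series to `ceiling(n / window)`. This is the
#' adjustment applied when autocorrelation is detected: averaging over
#' the correlated span restores approximate independence before the
#' trend test.
#'
#' @param x Numeric vector.
#' @param window Block length, `>= 1`.
#' @return Numeric vector of length `ceiling(length(x) / window)`.
#' @examples
#' average_adjust(c(2, 4, 6, 8, 10), 2)  # 3, 7, 10
#' @export
average_adjust <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != round(window)) {
    abort("window must be a positive integer",
          class = "salmonmme_parameter_error")
  }
  x <- as.numeric(x)
  if (window == 1) return(x)
  grp <- (seq_along(x) - 1) %/% window
  as.numeric(tapply(x, grp, mean, na.rm = TRUE))
}

#' Autocorrelation-adjusted Mann-Kendall trend test
#'
#' The full trend-testing procedure: diagnose autocorrelation; if the
#' lag-1 correlation is significant, block-average over the indicated
#' window, re-diagnose, and iterate (up to `max_rounds`); then run the
#' Mann-Kendall test on the (possibly averaged) series. The adjustment
#' trail — windows applied each round and the resulting sample size —
#' is recorded on the result for auditability.
#'
#' @param x Numeric vector or `event_series`.
#' @param max_lag,alpha Passed to [autocorrelation_diagnose()].
#' @param max_rounds Cap on diagnose/average iterations (default 3).
#' @return An `mk_trend`; `$adjustment` lists `window` (total averaging
#'   applied, 1 if none), `windows` per round, `n_original` and `rounds`.
#' @export
trend_test_pipeline <- function(x, max_lag = 12, alpha = 0.05,
                                max_rounds = 3) {
  if (inherits(x, "event_series")) x <- x$value
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n0 <- length(x)
  windows <- integer(0)
  rounds <- 0L
  repeat {
    if (length(x) < 3) {
      abort("averaging exhausted the series below n = 3",
            class = "salmonmme_data_error")
    }
    if (rounds >= max_rounds || length(x) < 4 || sd(x) == 0) break
    diag <- autocorrelation_diagnose(x, max_lag = max_lag, alpha = alpha)
    w <- attr(diag, "window")
    if (w <= 1) break
    x <- average_adjust(x, w)
    windows <- c(windows, w)
    rounds <- rounds + 1L
  }
  res <- mann_kendall(x)
  res$adjustment <- list(
    window = if (length(windows)) prod(windows) else 1L,
    windows = windows, n_original = n0, rounds = rounds
  )
  res
}

#' Lowess smooth of a trend for display
#'
#' Locally weighted linear regression (tricube weights, degree 1,
#' robustness iterations as in `stats::lowess`) evaluated at each `x`.
#' Used only to visualize trends; inference always comes from the
#' Mann-Kendall machinery.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param frac Smoother span in (0, 1], the fraction of points in each
#'   local fit (default 2/3).
#' @return Numeric vector of fitted values aligned with the input `x`.
#' @export
lowess_smooth <- function(x, y, frac = 2 / 3) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("x and y must have the same length",
          class = "salmonmme_parameter_error")
  }
  if (length(x) < 3) {
    abort("need at least 3 points", class = "salmonmme_data_error")
  }
  if (frac <= 0 || frac > 1) {
    abort("frac must lie in (0, 1]", class = "salmonmme_parameter_error")
  }
  fit <- lowess(x, y, f = frac)
  # lowess returns values at sorted unique-ish x; map back to input order
  idx <- order(x)
  out <- numeric(length(x))
  out[idx] <- fit$y
  out
}
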