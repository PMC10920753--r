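---
title: "Methods: trend and maximum-loss analysis of salmon mass mortality events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend and maximum-loss analysis of salmon mass mortality events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmonmme)
```

## The problem

Farmed-salmon producers report mass mortality events (MMEs) — episodes in
which large numbers of fish die in a short period — but jurisdictions define
and report them inconsistently: some countries report per production site at
monthly or finer resolution, others aggregate to counties or to whole years.
`salmonmme` implements a country-by-country analysis that works *within* each
country's reporting standard and asks two questions:

1. **Trend**: are the most severe loss events becoming more frequent, and is
   the upper bound of per-event loss growing?
2. **Tail risk**: how large could a single event (or a year of losses, for
   yearly reporters) plausibly get, and how does that compare with the loss
   thresholds that companies or counties themselves use to define an MME?

Rather than imposing a global MME definition, the analysis isolates each
country's top fraction of events by fish lost — 10% for sub-yearly reporters,
50% where yearly aggregation leaves on the order of ten records — and tracks
when those events occur and how big they are.

## Data model

A `MortalityEvent` is one reported loss record: country, reporting unit
(production site or county), period start date, native reporting resolution
(`submonthly`, `monthly`, `yearly`), and a non-negative integer count of fish
lost, with optional coordinates. Records are validated on ingestion
(`read_events()` with a user-editable column-mapping schema); rows that fail
validation are collected with row numbers and reasons, never silently
dropped. Yearly records are anchored to January 1 and sub-monthly records are
binned to the first of their month, so downstream aggregation works on a
clean monthly or yearly grain.

`aggregate_events()` produces regular series of per-period counts, maxima or
sums. Two conventions matter and are deliberate:

* A period with **no events counts as zero** in a frequency series — an
  absence of extreme events is real information.
* A period with no events is **missing** in a maxima or sum series — the
  maximum of an empty set is undefined, and imputing zero would fabricate a
  low observation and bias the trend test toward decline.

## Trend testing

The frequency and maxima series are tested for monotonic trend with the
Mann–Kendall statistic

$$S = \sum_{i<j} \operatorname{sgn}(x_j - x_i), \qquad
\operatorname{Var}(S) = \frac{n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)}{18},$$

where the $t_g$ are tie-group sizes; $Z$ carries the classical $\pm 1$
continuity correction and $p$ is the two-tailed normal probability. The
reported correlation is Kendall's tau-b, tie-corrected in the values (the
time index is untied by construction). Count series are full of ties, so the
tie corrections are not a refinement here but essential.

A seasonal variant of the test is deliberately **not** offered. Salmon
mortality can be seasonal, and a non-seasonal test facing seasonal variation
has *more* unexplained variance, making it conservative: it is less likely to
declare a trend, which is the right failure direction for a surveillance
analysis. Sen's slope and change-point detection are likewise out of scope —
the question is monotonic direction, not rate.

Mann–Kendall assumes independent observations, which monthly event counts
can violate. `trend_test_pipeline()` therefore first diagnoses serial
correlation (`autocorrelation_diagnose()`: sample autocorrelations against
the large-sample band $\pm z_{1-\alpha/2}/\sqrt{n}$, default lags 1–12 for
monthly data), and where the lag-1 correlation is significant it
block-averages the series over the correlated span (`average_adjust()`:
non-overlapping means, trailing partial block averaged over its actual
length), re-diagnoses, and only then tests. The averaging trail (window,
original and final $n$) is recorded on every result so a reader can see
exactly what was tested. Iteration is capped at three rounds; in practice one
round suffices, and the cap prevents a pathological series from being
averaged into nothing.

Lowess smoothing (`lowess_smooth()`, tricube-weighted local linear fits,
default span 2/3) is provided strictly for display; no inference ever reads
it.

On 10,000 simulated iid Gaussian null series of length 60 the full pipeline
rejects at about 4.6–4.8% for nominal $\alpha = 0.05$ — slightly conservative,
as the continuity correction predicts (the acceptance script recomputes this
rate on every run).

## Extreme-value analysis

Maximum potential loss is estimated by peaks-over-threshold: the threshold
$u$ is the empirical $(1 - f)$ quantile of the loss magnitudes (type-7
order-statistic interpolation; exceedances strictly above $u$), with $f$ the
same top fraction used for frequency tracking, so "an extreme event" means
the same thing in both halves of the analysis. Exceedances $y_i = x_i - u$
are fitted to the generalized Pareto distribution by maximum likelihood,

$$\ell(\xi,\sigma) = -m\log\sigma - (1+1/\xi)\sum_i \log(1+\xi y_i/\sigma),$$

with the exponential limit handled analytically at $\xi = 0$. The optimizer
is bounded quasi-Newton on $(\xi, \log\sigma)$ with a shape box of
$[-0.9, 0.95]$, started from probability-weighted moments plus four
perturbations (a derivative-free fallback catches ill-conditioned starts);
convergence, iteration counts and boundary contact are recorded on the fit.
Fewer than five exceedances is a refusal, not a fit.

Risk is summarised as Value-at-Risk and Expected Shortfall:

$$\mathrm{VaR}_q = u + \frac{\sigma}{\xi}\Big[\big(\tfrac{n}{n_u}(1-q)\big)^{-\xi} - 1\Big],
\qquad
\mathrm{ES}_q = \frac{\mathrm{VaR}_q}{1-\xi} + \frac{\sigma - \xi u}{1-\xi},$$

where $n/n_u$ converts tail probability to exceedance probability. The
default confidence level is $q = 0.999$: the point estimate is the expected
loss within the worst 0.1% of cases, bounded below by the 1/1,000-event
return level and above by the 1/10,000-event return level
($q = 0.9999$). $\xi \ge 1$ (infinite conditional mean) raises an error
rather than returning a clipped number. Per-country summaries
(`country_risk_summary()`) use per-event losses for sub-yearly reporters and
yearly summed losses for yearly reporters, and compare the ES point estimate
against the mean of the site-defined MME thresholds when a threshold table is
supplied.

No uncertainty intervals are attached to $(\hat\xi, \hat\sigma)$ by default;
the objects carry enough bookkeeping that a bootstrap over exceedances can be
layered on, but tail bootstraps on a few dozen exceedances are fragile and
are better left an explicit user decision.

## The synthetic generator

`generate_events()` emulates the *statistical* structure of a national MME
record stream, not fish biology. Per-period counts are Poisson with mean
$\exp\{\log\lambda_t + A\sin(2\pi t/12) + \varepsilon_t\}$ where
$\lambda_t = \lambda_0 + \beta_\lambda (t-1)$ (floored at zero), and
$\varepsilon_t$ is AR(1) noise with lag-1 correlation $\phi$ injected on the
latent log-rate so counts stay integer and non-negative. The noise scale is
a design choice of the generator: its stationary standard deviation
(`rate_noise_sd`, default 0.25) is active only when $\phi > 0$, so the plain
configuration ($\phi = 0$, $A = 0$, $\beta_\lambda = 0$) is *exactly*
homogeneous Poisson — the dispersion tests depend on that — and the noise is
mean-corrected by $-\mathrm{sd}^2/2$ so the expected rate stays $\lambda_t$.

Magnitudes come from one of two families, because real MME magnitudes have
no agreed distribution: a lognormal, or a composite with a uniform body on
$(0, u)$ and, with probability `tail_fraction`, an exact GPD tail above
$u$. The composite's tail is GPD *by construction*, so
`analytic_tail_risk()` gives closed-form VaR/ES truth against which the whole
pipeline (threshold selection → MLE → ES) can be scored — the package's
strongest self-test. The uniform body is deliberately stylized; it only has
to keep the body below the threshold.

One seed drives two independent sub-streams (counts, then magnitudes), so
changing the magnitude model never perturbs event times. Fixed seed means
byte-identical output.

What the generator does **not** emulate: reporting gaps and late records,
multi-site spatial correlation, jurisdiction changes mid-series, and
magnitude–frequency coupling. Passing tests on synthetic data therefore
validate the statistical machinery, not any claim about real national
datasets.

## Problem sizes and numerical choices

The validation suite uses: 10,000 random series (lengths 3–12) for the
brute-force Mann–Kendall oracle; 10,000 null replicates of length 60 for the
type-I error of the adjusted pipeline; $n = 10^4$ GPD samples for parameter
recovery ($\hat\xi$ within $\pm 0.05$, $\hat\sigma$ within 5%); $n = 10^6$
draws for the Monte-Carlo VaR/ES oracles; and a synthetic country of roughly
60,000 events (about 6,000 tail exceedances) for end-to-end Expected
Shortfall recovery within 15% of analytic truth. These sizes make the
stochastic checks stable without being wasteful.

Ties at the top-fraction cutoff are broken by earlier period, then
lexicographic unit label — deterministic and reproducible. The empirical
threshold uses R's default type-7 quantile and *strict* exceedance, recorded
in the output. Degenerate inputs fail loudly: constant series (undefined
autocorrelation), all-equal samples (zero exceedances), series shorter than
three, infinite-mean shapes.

## Limitations

* The block-averaging adjustment trades sample size for independence; for
  short, strongly autocorrelated series (yearly reporters) the resulting
  tests have little power, and results there are illustrative.
* ES point estimates inherit the usual POT sensitivity to threshold choice;
  the top-fraction convention makes the choice transparent rather than
  optimal.
* GPD parameter uncertainty is not propagated into VaR/ES; the return-level
  bounds reflect tail probability, not estimation error.
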