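---
title: "Individualized temperature anomalies: model, construction choices, and checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized temperature anomalies: model, construction choices, and checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acclimate)
```

## The model and its assumptions

`acclimate` studies the effect of *temperature anomalies* — recent weather
minus a historical reference — on subjective well-being (SWB), with the
reference individualized: each respondent is compared against the average of
the same calendar window over every year of their own life in their own
county. The estimating equation is a linear two-way fixed-effects panel
model,

$$ y_{ijt} = \alpha + \beta_1 f(\mathrm{temp}_{ijt}) + X_{ijt}\rho
  + W_{ijt}\sigma + \gamma_i + \theta_t + \varepsilon_{ijt}, $$

with individual effects $\gamma_i$, exact-interview-date effects $\theta_t$
(calendar-date dummies nest year, month, day-of-week and holiday effects),
individual controls $X$ (income, age, marital status, education, employment,
a recent-discomfort indicator), weather controls $W$ up to second order, and
survey weights. The 1–5 ordinal outcome is modelled linearly. Errors are
clustered two-way at the county and interview-date levels, the two dimensions
along which the exposure varies.

The identifying assumption is the usual one in this literature: conditional
on individual and date effects and the controls, short-run deviations of
weather from a person's historical experience are as good as random. The
individualized reference strengthens this: two neighbours interviewed the
same day have different anomalies whenever their ages differ, so the
coefficient is not identified off location-wide shocks alone.

## Exposure windows and reference schemes

**Window convention.** The exposure window is the `window_days` (default 30)
calendar days *ending on and including* the interview date. Historical
windows transpose the window's month–day boundaries — not day-of-year — to
each earlier year; a Feb 29 inside a transposed window is dropped in
non-leap years, so historical windows can differ in length by one day.
Window means over contiguous daily series are computed from cumulative sums,
so scheme sweeps over hundreds of thousands of person-year windows are
O(1) arithmetic per window.

**Reference schemes.** Four aggregations of the per-year window means:

| scheme | years averaged | role |
|---|---|---|
| `lifetime` | birth year … interview year − 1 | the individualized reference |
| `fixed_period(a, b)` | a … b (truncated before the interview year, with a warning) | the no-updating benchmark |
| `preceding_years(n)` | interview year − n … interview year − 1 | updating but not individualized |
| `cumulative_age(m)` | birth year … birth year + m − 1 | early-life-only references |

Two exact coincidences double as tests: `preceding_years(n = age)` and
`cumulative_age(m ≥ age)` both equal the lifetime reference. The
*years-missed rate* $|age - n| / \max(age, n)$ measures the mismatch of a
fixed-length window; the single formula covers both under-coverage (a
50-year-old on 25 preceding years misses 50%) and over-inclusion (a
20-year-old on 25 years: 5/25 = 20%).

References never include the survey year itself ("up to the year
immediately preceding" the interview); a fixed period reaching past that
boundary is truncated with a warning rather than silently used.

**Anomaly transforms.** `split_sign()` decomposes the anomaly exactly into a
hotter-than-expected part $\max(a, 0)$ and a colder-than-expected part
$\min(a, 0)$. `day_count_anomaly()` instead counts window days whose
temperature exceeds the month–day climatology over a fixed span of years —
robust to a few extreme days. Anomalies are kept in °C with no
standardization; their mean and SD are attached as metadata.

## What the synthetic world emulates — and what it does not

The generator produces every input at configurable scale with known ground
truth:

* **Geography** on a planar map in km (no geodesy; the interpolation
  contract is unchanged). Stations and counties are assigned to climatic
  regions by proximity to region centres; one station is pinned to each
  centre so no region is station-free.
* **Station temperature** = regional base + seasonal cosine (amplitude
  10 °C, peaking mid-July) + secular trend (0.02 °C/yr, the 0.2 °C/decade
  rate of recent decades) + a *region-month anomaly* (SD 1.2 °C) + a
  per-station offset + daily noise (SD 2 °C). The region-month component is
  essential: weather has a red spectrum, and without persistent warm/cold
  spells 30-day window means barely vary, anomalies are almost never
  negative, and sign-split designs degenerate. With it, synthetic anomalies
  have SD near 1 °C and straddle zero, matching the dispersion such surveys
  observe. Auxiliary variables (wind, humidity, precipitation, sunshine) are
  schematic covariates correlated with temperature, not physics.
* **The panel**: respondents fixed at their birth county (the estimation
  sample is restricted to non-migrants by construction), three waves
  (2010/2014/2018), birth years 1955–1990 so every lifetime is covered by
  the 1951–2018 weather record, and interviews drawn May 1–Oct 31 — the
  season in which such surveys are predominantly fielded; the exact
  within-season distribution is a modelling choice. Interviews fall on a
  limited set of distinct field dates per wave (default 20), as survey teams
  interview many respondents per field day; this keeps exact-date fixed
  effects identifiable at any sample size.
* **The outcome** is generated by the estimating equation itself (true
  anomaly effect −0.023 SWB per °C by default, noise SD 1). Discretization
  to the 1–5 scale is off by default so recovery checks are clean; when
  enabled, rounding attenuates the recoverable coefficient toward zero — a
  property the tests verify qualitatively.
* **Scenario ensembles**: annual regional temperatures 2015–2100 under
  net-zero (warming decelerates to a mid-century plateau), middle-of-the-road
  (steady 0.025 °C/yr) and high-emissions (accelerating) archetypes, each
  paired with a consistent 1950–2014 historical backcast. Model spread
  enters through per-model level offsets and slope multipliers; shapes are
  otherwise deterministic so plateau/acceleration properties hold exactly.

Passing tests on this world show the *method* is implemented correctly and
recovers known effects under realistic dispersion; they do not show that any
particular real-world dataset satisfies the identifying assumptions, and the
generator deliberately omits migration histories, humidity physics, real
geography and demography.

## Estimation: numerical choices

* **Fixed-effect absorption** by alternating weighted group demeaning to
  tolerance 1e-10 (max 1000 sweeps; non-convergence is an error reporting
  the last delta). A dummy-variable least-squares fit is the small-instance
  oracle: the tests require agreement to 1e-8 on every random instance up to
  200 rows. Observations that are singletons in either dimension contribute
  nothing after demeaning and are dropped iteratively and counted.
* **Rank safety.** Controls with no within variation (age is exactly
  absorbed by person plus date effects; any person-constant column likewise)
  are dropped with a message, as are controls that are collinear after
  demeaning; a collinear *temperature term* is a hard error. Empty
  temperature bins are dropped with a message.
* **Covariance**: Cameron–Gelbach–Miller two-way clustering,
  $V = V_a + V_b - V_{ab}$, each term a one-way cluster sandwich with
  finite-cluster correction $\frac{G}{G-1}\frac{N-1}{N-K}$. $K$ charges the
  explicit regressors only — the convention of the standard implementations —
  because both absorbed dimensions are nested inside their cluster
  dimensions (persons within counties, dates within dates). Simulation at
  study scale puts 95% interval coverage at ~94% under this convention
  (~99%, conservative, when absorbed effects are charged as well);
  `twoway_cluster_cov(df_k = )` exposes the choice. If the combined matrix
  is not positive semi-definite, negative eigenvalues are floored at zero
  and the repair is recorded. Inference uses a t distribution with
  $\min(G_a, G_b) - 1$ degrees of freedom. Significance stars follow the
  0.01/0.05/0.1 convention; no multiple-testing correction is applied, as is
  standard for coefficient tables of this kind.

## Projections

The projection side deliberately operates on *annual* mean temperatures
(the resolution of scenario products), not 30-day windows — a documented
divergence from the estimation side. Each projection year's representative
agent has the population's average age (rounded to an integer for birth-year
arithmetic); their *updating reference* is the mean annual temperature over
their lifetime so far, which requires the historical backcast the generator
supplies. The *fixed reference* is the 1980–2000 mean. Impacts are
`beta_hat × anomaly`, exactly linear in the estimated effect, ensemble
means are arithmetic over models, and the *catch-up year* is the first year
after which the ensemble updating anomaly stays below 0.05 °C in absolute
value — warming slow enough for acclimatization to have fully caught up. The
0.05 °C threshold is a package default (no numeric criterion is standard);
it is configurable, and under a linear trend of slope $m$ with constant age
$a$ the updating anomaly equals $m(a+1)/2$ exactly, which anchors the scale.

## When is the individualized model just location fixed effects?

A location-FE regression of well-being on temperature levels implicitly
compares temperature to a location average, so one may ask when it coincides
with the individualized-anomaly regression. Exactly when the personalized
reference is absorbed by the fixed effects — which requires three data
conditions simultaneously: everyone in a city interviewed on the same date,
everyone the same age, and every interview after the respondent's birth
month (so the birth year belongs to every reference window; a respondent
interviewed before their birth-month anniversary was not alive during the
birth-year window, which `model_comparison_simulation()` encodes by starting
their reference the following year).

The simulation demonstrates the knife-edge: city weather is a city base
plus a common seasonal cycle and common national year shocks, with
city-specific innovations only in the final survey year — so current
exposure varies across cities while every reference window stays additive in
city and wave. Both models are fitted exactly (dummy least squares) with
city and wave effects, the time resolution the location-FE benchmark
affords. With all three conditions held the two estimates agree to machine
precision; violating any one (heterogeneous ages, scattered interview dates,
or births late in the year) leaves individual-level reference variation
behind and the estimates separate by far more than the 1e-6 comparison
tolerance.

## Degenerate inputs and refusals

Daily series with duplicate dates or gaps are errors — the package never
imputes weather. Windows or reference years outside the series coverage
raise errors naming the offending county-date or year (respondents born
before the record starts need a restricted sample, which the panel
generator's default birth range respects). Interpolation with no reporting
station is an error; a county within one metre of a station takes the
station value exactly. Clustering with a single cluster in a dimension is
refused with advice to use one-way clustering.

## Problem sizes used in the checks

The package's calibration checks run at a deliberately desk-sized scale:
a 24-station / 40-county / 4-region world with 3000 respondents × 3 waves
(9000 observations) for parameter recovery — 100 replicates redrawing the
outcome over fixed covariates, requiring the mean estimate within two
Monte-Carlo standard errors of −0.023 and clustered-interval coverage inside
[90%, 99%] — and smaller worlds for structural and qualitative checks
(scheme coincidences, sweep attenuation, scenario catch-up). These sizes are
the package's own choices balancing statistical resolution against a test
suite that runs in well under a minute.

## Known limitations

The linear SWB model ignores the ordinal scale (the attenuation of the
discretized outcome is documented, not corrected); references are purely
local (no spatial smoothing across counties); the projection's
representative-agent construction abstracts from the age distribution; and
the synthetic weather, while dispersion-realistic, has no spatial
correlation structure beyond shared regional components.
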