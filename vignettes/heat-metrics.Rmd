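---
title: "Comparing prenatal heat-exposure metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing prenatal heat-exposure metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatbands)
```

## The problem

Epidemiological studies of prenatal heat exposure disagree about how "heat"
should be measured: daily maxima, daily minima, averages, heatwave counts, or
humidity-adjusted measures such as wet-bulb temperature. In temperate
climates these measures are tightly correlated and the choice matters little;
in tropical and arid climates they decouple, and the choice of metric can
change both the estimated magnitude of the heat-preterm-birth relationship
and whether any relationship is detected at all.

`heatbands` implements a complete, testable workflow for that comparison:

1. construct five candidate heat metrics from daily weather;
2. fit the same fixed-effects linear probability model of preterm birth once
   per metric, with cluster-robust inference;
3. select a preferred metric by a joint-significance screen followed by AIC
   ranking; and
4. translate the fitted coefficients into counterfactual preterm rates under
   typical hottest-9-months versus coolest-9-months gestational exposure.

Because the administrative perinatal data this design targets are
confidential, the package ships a first-class synthetic-data module: a
two-climate-zone weather generator and a birth-cohort generator with a known
exposure-to-outcome data-generating process (DGP). Every stage of the
pipeline is validated against that ground truth.

## The five heat metrics

Exposure is evaluated over a fixed 39-week (273-day) schedule from
conception, split into trimesters of 12, 14 and 13 weeks: half-open day
windows $[c, c+84)$, $[c+84, c+182)$, $[c+182, c+273)$. Conception is dated
by subtracting gestational age in weeks from the birth date. For each
trimester $k$ the metrics produce:

* **benchmark** — day counts of daily maximum temperature in 5-degree bands
  (<20, 20–24.99, 25–29.99, 30–34.99, 35–39.99, 40+; reference band
  25–29.99);
* **trimester_average** — the mean daily maximum temperature;
* **heatwave_count** — the number of heatwaves, where a heatwave is three or
  more consecutive days with a positive Excess Heat Factor (EHF);
* **max_and_min** — the benchmark bands plus day counts of daily minimum
  temperature in 5-degree bands (<5 … 25+; reference 15–19.99), separating
  peak heat from prolonged (overnight) heat;
* **wet_bulb** — band counts of daily average and daily maximum wet-bulb
  temperature (references 15–19.99 and 20–24.99 respectively), computed from
  air temperature and relative humidity with Stull's empirical
  approximation.

Bands are half-open $[\ell, u)$: the printed label "20–24.99" is the
interval $[20, 25)$, so a reading of exactly 25.0 belongs to the next band.
Reference (omitted) bands are materialised in the exposure tables and masked
only when the design matrix is built, which makes the conservation
invariant — per-trimester band counts summing to exactly 84/98/91 — directly
testable.

The EHF for day $d$ combines a significance term and an acclimatisation
term: with $T_3$ the mean daily-mean temperature over days $d-2 \dots d$ and
$T_{30}$ the mean over the 30 days ending at $d-3$,

$$\mathrm{EHF}_d = (T_3 - \bar T)\times\max(1,\ T_3 - T_{30}),$$

where $\bar T$ is a long-term location baseline. The default baseline is the
long-term location **mean** of daily mean temperature, following the verbal
definition this workflow targets; the operational heatwave-service
convention (95th percentile of daily means) is available via
`baseline = "p95"`. The 30-day window excludes the current 3-day block, and
the first 32 days of a series are unscored. Only the sign of EHF is consumed
downstream. With the mean baseline roughly half of all days have a positive
significance term, so detected "heatwaves" are considerably more frequent
than under the p95 convention (about 4–5 per pregnancy in the synthetic
world); this affects levels, not the validity of the count as a regressor.

Wet-bulb temperatures use Stull's (2011) single-equation fit, valid to about
1 °C for roughly 5–99 % relative humidity and −20–50 °C. Daily *maximum*
wet bulb is Stull at the daily maximum temperature and daily humidity. A
true daily *average* wet bulb requires sub-daily data; the package defines
it as Stull at the daily mean temperature, which preserves the monotone band
membership that the banded metric consumes.

## The regression model

For birth $i$ at location $j$ conceived on date $t$ (month $m$, year $y$):

$$\text{preterm}_i = \beta_0 + \sum_{k=1}^{3}\beta_{1k}\,\text{heat}_{tjk}
  + \beta_2 X_i + \gamma_{my} + \theta_{jm s_i} + \varepsilon_{ij}$$

a linear probability model (deliberately not a logit, so coefficients are
percentage-point effects and absorbed fixed effects are exact), with
covariates $X_i$ = first-pregnancy indicator, Aboriginal indicator and
one-hot 5-year mother-age bands (reference 25–29), month-year-of-conception
fixed effects $\gamma_{my}$, and location × conception-month × sex fixed
effects $\theta_{jms}$. Identification comes from day-to-day weather
variation within a location-month-sex cell.

Implementation choices, each covered by an oracle test against an explicit
dummy-variable regression:

* **Absorption.** The two fixed-effect groups are removed by alternating
  within-group demeaning (compiled sweep kernel), iterated until the largest
  per-sweep adjustment falls below $10^{-10}$ (cap 10,000 sweeps). Absorbed
  degrees of freedom are counted exactly as
  $L_1 + L_2 - (\text{connected components of the two factors' bipartite
  graph})$. Singleton cells are retained; they contribute zero within
  variation.
* **Rank handling.** Collinear columns (including columns demeaned to zero)
  are dropped by pivoted QR and logged.
* **Cluster-robust covariance.** Locations are grouped into geographic
  clusters of bounded 50-mile diameter (complete-linkage agglomerative
  clustering on great-circle distances — complete linkage is the one
  standard criterion whose merge height is exactly the cluster diameter, so
  cutting the dendrogram at 50 enforces the bound; "maximum 50-mile
  distance" could alternatively be read as a linkage threshold, which would
  allow larger diameters). The covariance is the cluster-summed sandwich
  with the Stata-areg small-sample factor
  $\frac{G}{G-1}\cdot\frac{N-1}{N-K}$, $K$ counting absorbed effects plus
  kept regressors, so results are comparable with the published-workflow
  convention.
* **Joint test.** The heat term-group is tested with a Wald statistic on the
  cluster-robust covariance, $F = b'V^{-1}b / q$ against $F(q, G-1)$.
  Cluster-robust joint tests with many restrictions relative to the number
  of clusters over-reject; with the package's simulated geography
  (41 clusters) the size is near nominal for small term groups (measured at
  about 6 % for $q = 3$) but materially inflated at $q = 30$. This is a
  property of the estimator, not of the implementation, and is why the
  size-calibration test uses a 3-term metric.
* **Fit statistics.** The within R² is computed on the demeaned data and
  adjusted for the number of non-absorbed regressors. The AIC uses the
  Gaussian log-likelihood from the residual sum of squares with parameter
  count = kept regressors + intercept + error variance; absorbed fixed
  effects are excluded from the penalty because every compared model shares
  the identical fixed-effect structure (a flag includes them for
  sensitivity). The AIC is therefore internally consistent for ranking,
  not comparable in absolute level with other software's bookkeeping.

## Metric selection

Stage one screens each metric by the joint F-test of its heat terms at
$\alpha = 0.05$ (the covariance used is cluster-robust, consistent with the
reported standard errors; a classical variant is available). Stage two ranks
survivors by AIC (lower is better). The within adjusted R² is reported and
used to annotate whether the two goodness-of-fit measures agree; when they
disagree the report says so loudly, but AIC decides, because it is the
measure with a principled penalty for comparing non-nested models of
different dimension. Ties break by fewer regressors, then name order, so
selection is deterministic and order-invariant.

## Counterfactual seasonal predictions

"Typical" exposure is the multi-year day-of-year climatology at each birth's
own location: per-calendar-day means of the base fields (maxima, minima,
humidity) over complete reference years, with derived fields recomputed from
the averaged base fields (never averaged post hoc) and February 29 filled
from February 28. Two scenarios re-date every pregnancy so that a 39-week
gestation ends mid-May (gestation spanning the hottest nine months) or
mid-November (the coolest nine months), and rebuild its exposure from the
climatology exactly as for real weather.

The predicted cohort rate under scenario $s$ is a partial-effect contrast:

$$\hat p_s = \bar y + \frac{1}{n}\sum_i (x_{i}^{(s)} - x_i)'\hat\beta_{1}$$

with only the heat terms swapped and everything else held factual, so fixed
effects and covariates cancel exactly in the hottest-minus-coolest
difference (asserted algebraically in the tests). Confidence intervals at
68/80/95 % come from the delta method on the heat-coefficient block of the
cluster-robust covariance; a parametric-simulation alternative (draws from
the coefficient distribution) is available and agrees with the delta method
within 10 % of half-width in the tests. Uncertainty in the observed baseline
rate $\bar y$ is not propagated — the intervals describe the
heat-coefficient-driven component only. Predicted rates (never the
difference) are clipped to $[0,1]$ for reporting, with a flag. Because the
contrast extrapolates within-cell daily-deviation slopes to a full seasonal
swing in exposure, scenario gaps can be large and seed-noisy under strong
planted DGPs; they are reported as model-implied quantities, not
calibrated targets.

## The synthetic world

`gen_weather()` draws, per location: daily maximum = annual cosine + AR(1)
Gaussian noise; diurnal range = its own seasonal cosine (peaking mid-dry
season in the tropical zone) + independent noise; minimum = maximum −
range; relative humidity = a seasonal cosine whose peak lags the temperature
peak + a coupling term proportional to the maximum's deviation from its
annual mean + noise, clipped to [0, 100].

The two default parameter sets emulate the study region: a tropical zone
(wet-season days about 26–32 °C with the central half of wet-season days
inside 25–33 °C, weak max/min correlation ≈ 0.75–0.88 produced by large
range noise, humidity negatively correlated with temperature through the
negative coupling) and an arid zone (summer days about 20–35 °C, winter
about 4–20 °C, strong max/min correlation ≈ 0.99 from small range noise).
What the generator does **not** emulate: spatial autocorrelation between
locations beyond shared zone parameters, rainfall, sub-daily structure,
multi-day synoptic persistence beyond AR(1), or trends. Passing tests
therefore demonstrate correctness of the estimators under a stylised but
structurally faithful climate, not climatological realism.

`gen_cohort()` samples conception dates uniformly over the configured
interval (sampling by conception date avoids fixed-cohort bias), assigns
locations, sex, and covariates, and draws preterm birth from a latent linear
probability: baseline 0.10 (the observed population rate) plus per-day band
effects plus covariate effects, clipped to [0, 1] with the clipping rate
recorded in the truth record (a logistic link is available for robustness
experiments). Gestational length is uniform over 28–36 weeks for preterm and
37–42 for term births — only the 37-week threshold matters downstream.
Stillbirths and plural births are ordinary records with flags. A
birthweight-like continuous outcome is generated from an analogous linear
model and top/bottom-coded at the 2.5th/97.5th percentiles.

By default the band effects act on exposures **centred within location ×
conception-month cells**. The uncentred parameterisation adds a large
location-seasonal shift to the latent probability, which either saturates
the [0, 1] clip (biasing recovery) or forces effects too small to identify;
the centred form puts the entire planted signal in exactly the within-cell
variation the fixed-effects estimator uses, keeps the cohort rate at the
baseline, and leaves the slope coefficients unchanged. The cell-level shift
it removes is precisely what the model's fixed effects would absorb.

The planted truth used throughout the validation suite loads mostly on
minimum-temperature bands (per-day effects of +0.5 pp for nights at or above
25 °C in trimesters 1–2, −0.3 to −0.4 pp for cold nights, with smaller
maximum-band effects of ±0.2–0.3 pp), i.e. a DGP in which prolonged
overnight heat matters — the pattern the combined max-and-min metric exists
to capture and the single-series metrics cannot.

## Validation design and problem sizes

The simulation-based checks run on a fixed synthetic geography of 28
tropical + 28 arid locations (41 geoclusters) with 9.5 years of daily
weather; conceptions span March 2001 – September 2008 so every 273-day
schedule and the 32-day EHF warm-up are covered. Sizes were chosen so each
property is measured where its asymptotics are trustworthy:

* **Oracle equivalence** — at a few hundred rows, the absorbed path equals
  explicit dummy-variable OLS with a hand-built cluster sandwich to 1e-6.
* **Parameter recovery** — 200 cohorts of n = 10,000: mean estimates within
  Monte-Carlo error of the planted truth; pooled 95 % CI coverage within
  [90 %, 98 %] (measured ≈ 94 %).
* **Test size** — 500 null cohorts of n = 8,000, 3-term metric: joint-F
  rejection within [3 %, 8 %] at the 5 % level. n = 8,000 keeps the
  $(N-1)/(N-K)$ correction (with ≈ 1,400 absorbed cells) from making the
  test conservative.
* **Selection consistency** — 100 cohorts of n = 10,000 under the planted
  max-and-min truth: the two-stage procedure selects `max_and_min` in at
  least 90 % (typically all) of replicates.
* **Counterfactual null** — 200 null cohorts: the 95 % interval for the
  hottest-coolest difference covers zero at its nominal rate.

## Known limitations

* The linear probability model can predict outside [0, 1]; fitted values are
  not clipped except in counterfactual summaries.
* The AIC's absolute level is convention-dependent (see above); only
  differences across metrics sharing the fixed-effect structure are
  meaningful.
* Joint cluster-robust Wald tests with q comparable to G over-reject; treat
  large-group F statistics as descriptive and rely on the screen mainly for
  small term groups, or increase the cluster count.
* Third-trimester exposure follows the fixed 273-day schedule even for
  preterm births (truncating at birth would make exposure mechanically
  depend on the outcome); `truncate_at_birth = TRUE` exposes the alternative
  reading for sensitivity analysis.
* Heatwave events straddling a trimester boundary are attributed to the
  trimester containing their start date, once.
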