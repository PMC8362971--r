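---
title: "Methods: temperature-driven phenology models, cohort simulation and risk mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-driven phenology models, cohort simulation and risk mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotherm)
```

## The problem

*Diachasmimorpha longicaudata* is a braconid parasitoid released widely
against tephritid fruit flies, in particular the invasive *Bactrocera
dorsalis*. Whether a release establishes depends first of all on
temperature: immature development, survival, adult lifespan and egg
production are all strongly temperature-dependent. `phenotherm`
implements the full workflow that turns constant-temperature laboratory
life tables into population-level predictions:

1. **fit** thermal response curves for every demographic trait,
2. **simulate** stochastic cohorts at constant temperatures to obtain
   the classical growth parameters ($r_m$, GRR, $R_0$, $T_c$, $D_t$,
   $\lambda$), and
3. **map** an establishment index (EI) and a generation index (GI) from
   monthly climate grids.

A synthetic-data generator with a known ground truth stands in for the
laboratory experiments, so the whole pipeline is testable end to end
without any external data.

## Thermal response models

**Development rate.** The degree-day model $r(T) = a + bT$ is fitted by
ordinary least squares to mean rates (reciprocal mean development
times); it yields the lower threshold $T_{min} = -a/b$ and the thermal
constant $k = 1/b$ degree-days. Because the rate–temperature curve is
only linear in its middle portion, `run_fit()` restricts this fit to
temperatures up to `linear_max_temp` (default 30&nbsp;°C). The full curve is
the Logan model
$$r(T) = \gamma\left\{e^{\rho T} - e^{\rho T_{max} - (T_{max}-T)/v}\right\},$$
which is exactly zero at the upper threshold $T_{max}$ and clamped to
zero above it. For a biologically sensible fit the boundary-layer decay
must outrun the exponential rise ($\rho v < 1$); accepted fits satisfy
this in practice.

**Immature mortality and fecundity.** Both are U-shaped/unimodal
responses. We model them behaviourally as a product of two logistic
terms,
$$g(T) = \frac{1}{\left(1+e^{-(T-c)/b_{low}}\right)\left(1+e^{(T-c)/b_{high}}\right)},$$
with mortality $m(T) = 1 - h\,g(T)/g_{max}$ and fecundity
$f(T) = h\,g(T)/g_{max}$. When the two widths differ the raw product's
extremum shifts away from $c$; the constructor computes that offset once
and re-centres the curve so the *stated* optimum (`t_opt` / `t_op`) is
exactly the extremum, with $h$ the peak survival (respectively peak egg
load). Mortality approaches 1 smoothly at both extremes; the derived
lethal temperatures are reported where the curve crosses a configurable
`lethal_level` (default 0.999). A smooth two-logistic shoulder cannot be
simultaneously near-total at 10&nbsp;°C and moderate at 15&nbsp;°C, so the cold
shoulder reaches ≈0.97 at 10&nbsp;°C under the reference parameterisation —
the closest the shape comes to "total mortality at 10&nbsp;°C" while leaving
development measurable at 15&nbsp;°C.

**Development-time and longevity distributions.** Cumulative completion
frequencies are modelled against $\ln$-time with one common slope $b$
and a per-temperature intercept $a_i$, under a logit
($F(x) = \text{logit}^{-1}(a_i + b\ln x)$) or complementary log-log
link. For the logit link the median is $e^{-a_i/b}$. Fitting maximises
the binomial likelihood of the cumulative counts (`glm` with
`cbind(k, n-k) ~ 0 + group + log(time)`). Sampling re-centres the fitted
shape on any target median, which is how the simulator interpolates
between experimental temperatures: the median comes from the Logan model
($1/r(T)$), the spread from the fitted common slope.

**Oviposition timing.** The cumulative proportion of a female's lifetime
eggs laid by *normalised* age $x$ (chronological adult age divided by
the expected longevity $1/s(T)$) is $F(x) = 1 - e^{-a x^b}$.

**Adult senescence.** The senescence rate (inverse expected longevity)
follows the Ratkowsky parabola $s(T) = b\,(T - T_b)^2$. The parabola
vanishes at its vertex, so predicted longevity diverges near
$T_b \approx 21$&nbsp;°C — a property of the functional form, not of the
insect (observed adult longevity never exceeded ~24 days). All
simulation code therefore caps the expected longevity at
`max_longevity` (default 25 days). Without the cap, females simulated at
21–24&nbsp;°C would lay eggs over thousands of days and the generation time
would explode mid-range instead of decreasing with temperature.

## Fitting machinery

Nonlinear families are fitted by bounded Levenberg–Marquardt
(`minpack.lm`) from a Latin-hypercube of 32 starting points (seeded;
`lhs`) over documented per-family parameter boxes. Two non-obvious
choices:

* **Profiled starts for Logan.** With only a few rate means the Logan
  SSE surface is multimodal in $T_{max}$ and contains a long flat ridge
  in $\gamma$. The fitter therefore also profiles $T_{max}$ over a
  0.5&nbsp;°C grid (three curated starts each, threshold pinned), frees all
  parameters from each profile solution, and restarts once any run that
  stops at the iteration cap on the ridge. This makes the recovered
  $T_{max}$ deterministic to ~0.001&nbsp;°C across seeds.
* **Binomial weights for mortality.** Mortality observations are
  proportions with very unequal binomial variances; `run_fit()` weights
  them by $n_i / (\hat p_i(1-\hat p_i))$ (clipped at the 0/1 edges).
  Weighting roughly halves the spread of the recovered optimum
  temperature.

$R^2$ is $1 - SSE/SST$ (computed on weighted sums when weights are
supplied; it can be negative for poor fits). AIC is
$n\ln(SSE/n) + 2p$ for least-squares fits and $-2\ln L + 2p$ for the
binomial distribution fits; only rank order is used, with ties
($|\Delta AIC| < 10^{-6}$) broken by higher $R^2$. An optional
augmentation point (e.g. anchoring the poorly sampled mortality curve at
23&nbsp;°C) enters the residual sum like a real observation, is weighted
like a typical one, and is flagged in the result; it is off by default
and its value must be supplied by the user.

## Cohort simulation and life-table parameters

`simulate_cohort()` advances `n_eggs` (default 200, 3 replicates) through
one generation at a constant temperature:

* sex is assigned to every egg (`sex_ratio`, default 0.5 — the
  experiments do not report one);
* immature survival is a single Bernoulli event at stage entry with
  probability $1 - m(T)$ (the data are one egg-to-adult mortality
  proportion per temperature, so distributing the hazard over days would
  add structure the data cannot support);
* survivors complete development at times drawn around the Logan median;
* adults die at ages drawn from the fitted longevity distributions
  around the capped senescence median;
* each female draws a lifetime egg total (Poisson by default,
  negative-binomial via `dispersion`) around the fecundity-curve mean
  and lays it over her lived days by inverse-cdf sampling of the
  oviposition schedule, truncated and *renormalised* to her realised
  lifespan.

The renormalisation means every drawn egg is laid, which makes the
stochastic $R_0$ agree with the closed form
$(1-m(T)) \cdot q \cdot f(T)$ — at the cost that a short-lived female's
realised schedule is a compressed version of $F(x)$. Because the median
lifespan sits at normalised age 1, where the reference schedule has only
reached $F(1) \approx 0.52$, this compression is the rule rather than
the exception; pooled cumulative egg curves therefore recover the truth
cdf only when laying is essentially complete before typical death (the
property test uses such a front-loaded schedule), and fitted oviposition
parameters under realistic settings absorb the truncation. This is the
same censoring any laboratory schedule fitted from observed females
carries.

The life table follows the **female line** (the standard convention):
$l_x$ is the survivorship of female-fated eggs (immature deaths placed
at their would-be emergence day) and $m_x$ the daughters per living
female per day. This keeps $R_0 = \sum l_x m_x$ equal to its closed-form
expectation even when male and female adult survival differ (a
whole-cohort $l_x$ would bias it). From the schedule:
$R_0 = \sum l_x m_x$, $GRR = \sum m_x$ (full simulated lifespan, as
censoring is not reported for the reference data),
$T_c = \sum x\,l_x m_x / R_0$, and $r_m$ solves the renewal equation
$\sum e^{-r_m x} l_x m_x = 1$ by bracketing plus root refinement to an
absolute residual below $10^{-10}$ (`method = "lotka"`, the default;
zero $l_x m_x$ terms are dropped so bracket expansion cannot produce
$0 \times \infty$). The textbook approximation $r_m = \ln(R_0)/T_c$ is
retained (`method = "approximation"`) because the two agree closely
whenever reproduction is concentrated in age, and because published
growth-parameter tables for this system are consistent with it.
$D_t = \ln 2 / r_m$ and $\lambda = e^{r_m}$ always follow the identities.
A cohort with no reproduction reports $R_0 = 0$ with `rm` flagged
undefined rather than erroring.

One global seed drives everything: per-temperature, per-replicate seeds
are derived with a Lehmer-style integer map (`derive_seed()`), and all
fitting/simulation code uses a local RNG state so library calls never
disturb the caller's stream.

## Establishment and generation indices

Monthly minimum/maximum layers are interpolated to 365 daily values by
periodic cosine easing anchored at mid-month (a day at a month's
midpoint takes exactly that month's value); the daily mean is
$(\min+\max)/2$. Cosine easing of a sampled annual cycle reconstructs a
sinusoid to within about 9% of its amplitude (≈0.45&nbsp;°C for a typical
5&nbsp;°C seasonal half-amplitude) — adequate for threshold counting, and the
error scales linearly with amplitude.

* **EI** = 1 − (lethal days)/365, where a day is lethal when the
  mortality curve at its mean temperature reaches `lethal_threshold`.
  The default threshold is 0.99 rather than literal 1.0 because the
  smooth curve approaches 1 only asymptotically; a configurable
  `"extremes"` mode also flags a day lethal when either daily extreme
  reaches the threshold. The year has 365 days, no leap days.
* **GI** = mean over days of $365/T_c(T_{day})$. $T_c(T)$ is built by
  simulating cohorts on a 1&nbsp;°C lattice and interpolating the mean
  generation time linearly; days outside the viable range contribute
  zero generations.
* **Classification** uses half-open intervals $[low, high)$ over five
  classes (unsuitable/marginal/suitable/highly suitable/optimal). Two
  break presets ship — `"strict"` (0.3, 0.45, 0.6, 0.8) and `"lenient"`
  (0.2, 0.4, 0.6, 0.8) — because both sets are in circulation for this
  index; neither is endorsed.
* Grids are read and written as ESRI ASCII rasters (12 tmin + 12 tmax
  layers per stack); derived rasters carry the input georeferencing
  unchanged, and scenario differencing refuses misaligned grids.

## The synthetic-data generator

`generator_truth()` bundles a complete truth model set
(`longicaudata_models()`) with the design of the emulated experiments:
immature cohorts at 15, 20, 25, 30, 35&nbsp;°C (150 eggs each by default) and
freshly emerged adults (50 per sex) at 15, 20, 25, 30, 32.5, 35&nbsp;°C —
adults are tested beyond the immature viable range, as in the real
design, which is why fecundity data exist at 35&nbsp;°C while no adult ever
emerges there. The reference parameter values are calibrated to the
species' reported biology: development between ~10 and 33.7&nbsp;°C
(thermal constant ≈333 degree-days; dev-time logit slope 15.56),
survival optimum at 28&nbsp;°C with effectively total mortality below
~7&nbsp;°C and above 34&nbsp;°C, peak fecundity ≈220 eggs near 28&nbsp;°C (≈154 at
25&nbsp;°C, a handful at 35&nbsp;°C), senescence parabola vertices near 21&nbsp;°C and
longevity spread slopes 2.41 (logit, females) and 1.49 (cloglog, males).

What the generator does **not** emulate: daily host-larva supply caps
(a `daily_cap` option exists but is off by default), encapsulation and
host-quality effects, photoperiod or humidity covariates, and any
between-replicate environmental variation. Passing recovery tests on
synthetic data therefore shows the estimators are consistent under the
model's own assumptions — not that real rearing data are this clean.

## Numerical choices and test problem sizes

* All evaluations clamp to their codomains (rates ≥ 0, proportions in
  [0, 1]); temperatures must be finite, and evaluations are intended for
  [−10, 60]&nbsp;°C.
* Simulated times are ceiled to the daily grid (`time_step`, default
  1 day), matching daily observation schedules.
* The test suite runs recovery studies at deliberately modest sizes —
  100 seeded replicates for the linear thresholds, 50 for the Logan and
  mortality designs (12 starts each), 10 full generate→fit round trips
  at 200 eggs per temperature, one 10⁵-egg cohort for the $R_0$
  consistency check, and 100×100 synthetic grids for mapping — chosen to
  exercise every claim at sizes a routine run completes comfortably.
* The generate→fit round-trip design adds rearing temperatures at 28 and
  32.5&nbsp;°C: with no observation near the survival optimum its location is
  weakly identified by any estimator, which is a property of the
  5-temperature experimental design, not of the fitter.

## Known limitations

* The mortality/fecundity curve family is a behavioural stand-in chosen
  for its shape properties; its parameter values are not comparable to
  other software's parameterisations of similar curves.
* Growth parameters at strongly non-viable temperatures are dominated by
  a handful of surviving females and are reported with correspondingly
  large replicate SEs.
* The EI/GI machinery assumes immature lethality is instantaneous at the
  daily scale and ignores acclimation, microclimate and moisture.
* GeoTIFF input is not supported; convert rasters to ESRI ASCII grids
  first.
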