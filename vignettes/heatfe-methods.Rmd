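---
title: "Methods: temperature and county-level death rates with two-way fixed effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature and county-level death rates with two-way fixed effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatfe)
```

## The model

`heatfe` estimates how monthly ambient temperature relates to a monthly
county-level outcome rate — the motivating application is the death rate
from police violence in US counties, defined as monthly deaths divided by
county population. The core regression is a weighted panel model with two
high-dimensional fixed-effect dimensions:

$$ y_{imst} = f(\mathrm{temp}_{imst}) + \beta\,\mathrm{prec}_{imst}
   + \delta_{im} + \alpha_{st} + \mu_{imst} $$

where $i$ indexes counties, $s$ states, $m$ calendar months and $t$ years.
The county-by-month intercepts $\delta_{im}$ absorb each county's own
seasonal cycle (and any time-invariant county attribute), and the
state-by-year intercepts $\alpha_{st}$ absorb state-level annual trends.
Identification therefore comes from within-county deviations of a month's
temperature from that county's typical value for that calendar month,
net of the state-year level. Observations are weighted by county
population, and all inference clusters standard errors by county, allowing
arbitrary serial correlation within a county's series.

The temperature response $f$ is either linear — its coefficient $\gamma$ is
then the effect of a 1 °C deviation — or a flexible basis: the default
nonlinear candidate is a natural cubic spline with three knots at 0, 10 and
20 °C, alongside a seven-knot natural spline (knots evenly spaced from −17
to 33 °C), a cubic polynomial, and a cubic B-spline. Candidates are
compared by AIC under identical fixed effects, weights, clustering and
estimation rows.

## Estimation

Fixed effects are absorbed by iterated within-group demeaning (alternating
weighted projections over the two grouping dimensions) rather than by
estimating dummy coefficients; the sweep repeats until no cell moves by
more than `demean_tol` (default `1e-10`) relative to its column scale, and
errors rather than returning a half-converged answer. On the demeaned data
a weighted least-squares solve gives coefficients identical (to numerical
tolerance) to the full dummy-variable regression; the test suite asserts
this equivalence against a dense `lm()` oracle at a relative tolerance of
`1e-8` on panels up to 2,000 rows.

The covariance is the CR1 cluster-robust sandwich: weighted score vectors
are summed within counties, and the small-sample factor
$\frac{G}{G-1}\cdot\frac{N-1}{N-K}$ is applied, where $K$ counts the slope
terms plus the absorbed fixed-effect degrees of freedom. That absorbed rank
is computed exactly as
(county-month cells) + (state-year cells) − (connected components of the
bipartite graph linking the two dimensions), via union-find; with counties
nested in states the component count equals the number of states. With
every observation its own cluster the estimator reduces to HC1, which the
tests verify against the `sandwich` package. Singleton cells are retained —
they contribute zero after demeaning.

Model comparison uses the Gaussian AIC
$n\log(\mathrm{wSSR}/n) + 2k$ with $k$ the number of slope parameters only.
The absorbed fixed-effect dimension is identical across the candidates
being compared, so its parameter count is a common additive constant; the
value is meaningful only for comparing models on the same response, rows
and weights, and is documented (and tested) as such. Weights are rescaled
to mean one internally, so coefficients, covariance and AIC comparisons are
invariant to the weight scale. An AIC caveat worth stating plainly: when a
smaller candidate is nested in a larger one and the extra parameters are
truly useless, AIC still prefers the larger model with probability
$\approx P(\chi^2_1 > 2) \approx 16\%$ per extra parameter — model
selection by AIC is consistent in signal, not conservative under the null.

## Response curves

Curves are anchored at a reference temperature (10 °C by default): the
reported effect at $T$ is $b(T)'\hat\gamma - b(\mathrm{ref})'\hat\gamma$,
exactly zero at the reference. Pointwise confidence bounds come from the
delta method on the cluster-robust covariance,
$(b(T)-b(\mathrm{ref}))'\,V\,(b(T)-b(\mathrm{ref}))$, at ±1.96 SE. For the
three-knot natural spline the outer knots (0 and 20 °C) are the boundary
knots, so the basis has two columns and extrapolates linearly beyond them;
grid points outside the observed sample range are flagged rather than
suppressed. A histogram of sample temperatures over the grid bins
accompanies every curve.

## Displacement (lag/lead) effects

Temperature shifts may displace rather than add events, so the linear model
is extended with the previous and next month's exposures (lags
$L \in \{-1, 0, 1\}$, extensible to ±2 for robustness checks). Lags are
taken strictly within a county's consecutive month sequence — a calendar
gap is an error, never a silent shift — and rows missing a requested lag
are dropped with a logged count (per-specification complete cases; a
common-sample comparison can be forced by fitting the widest lag set
first). The net effect is the sum of the current-month and previous-month
coefficients, with variance $V_{00} + V_{11} + 2V_{01}$ from the clustered
covariance; leads act as a placebo check and are centered on zero when the
truth has none.

## Heterogeneity

Three complementary designs, all under the standard fixed effects, weights
and clustering:

* **Interaction models**: temperature and precipitation each interacted
  with a binary indicator (e.g. above/below the population-weighted sample
  mean of precipitation — the weighted mean is this package's reading of
  "average", chosen to match the estimator's own weighting). The
  indicator's main effect is kept when it varies within fixed-effect cells
  and reported as absorbed when it does not (any county-constant
  indicator).
* **Binned models**: the panel split by temperature (<10, 10–20, >20 °C),
  precipitation (<50, 50–100, >100 mm) or population (<1, 1–5, >5 million)
  and the linear model refit per bin; population bins attach to counties,
  the others to rows. Empty bins are reported with `n = 0`; bins with fewer
  than two county clusters return no estimate.
* **Categorical decompositions**: temperature and precipitation fully
  interacted with year, state, calendar month, or climate region, using
  cell-means coding — each category gets its own slope column, so the
  reported estimates are per-category slopes with no reference category to
  misread. A lookup for the nine NOAA climate regions of the contiguous US
  ships with the package.

Because the underlying rate scale of a given dataset is arbitrary, subgroup
tables carry both the raw per-°C effect and the effect as a percent of the
(sub)sample's weighted mean rate.

## Projection of excess deaths

County-level warming $\Delta T_c$ per climate model (end-of-horizon mean
minus baseline mean, aggregated from grid cells by renormalized overlap
weights) is expanded into per-year paths. The within-horizon shape is not
part of the climate input, so it is an explicit modelling choice: a linear
ramp from 0 at the base year by default, with a `step` alternative; the
cumulative totals are roughly twice as large under `step`, which is why the
choice is a visible argument and not a constant. Cumulative excess deaths
follow

$$ E = \sum_{t} \mathrm{pop}_{ct} \cdot \Delta T_{ct} \cdot \beta \cdot 12 $$

with $\beta$ the net (current plus previous month) per-°C change in the
monthly rate. Applying an annual-mean warming to a monthly coefficient and
multiplying by 12 months assumes uniform warming across the seasonal cycle;
`months_per_year` is exposed for sensitivity analysis. `beta_scale`
declares the rate denominator (1e7 person-months by default) so that a
mismatch between the fitted rate units and person units is an error, not a
silent factor-of-ten.

Uncertainty combines two sources: a county-level cluster bootstrap
(counties resampled with replacement, each copy refit as its own
fixed-effect unit and cluster, the net effect retained per draw) crossed
with the climate-model ensemble, giving $B \times M$ trajectories — the
conventional choice $B = 1000$, $M = 30$ yields a 30,000-member ensemble,
while tests run at $B = 200$, $M = 10$. Summaries report the median,
interquartile range and 2.5/97.5 percentiles per year. A failed bootstrap
refit is redrawn with a capped retry count; with $B = 1$ the single
trajectory uses the full-sample point estimate.

## The synthetic data generator

Every stage is validated against panels whose truth is known. The generator
produces a balanced county×month panel from

$$ y = \mathrm{base} + f(\mathrm{temp}) + \textstyle\sum_L \gamma_L
   \mathrm{temp}_{m-L} + \beta_p\,\mathrm{prec} + \delta_{im} + \alpha_{st}
   + \varepsilon,\quad \varepsilon \sim N(0, \sigma) $$

with county mean temperatures uniform on 2–22 °C, a sinusoidal seasonal
cycle of ±12 °C peaking in July, and 2 °C month-level noise — a caricature
of CONUS climate with realistic within-county variation. Rates are
expressed per 10⁷ person-months, which puts US-scale police-violence death
rates (baseline 3 per 10⁷ person-months) and their per-°C coefficients on
an O(1) scale; the scale is configuration, not a constant, because real
datasets differ. Default panel dimensions are 100 counties in 10 states
over 10 years; the model-selection studies use 400 counties over 12 years
(57,600 rows) so that spline curvature is decisively identifiable.

The `confounded` switch draws the county-month intercepts with correlation
0.5 to each cell's mean temperature, so pooled OLS is visibly biased while
the within estimator stays consistent — the contrast the fixed effects
exist to demonstrate. The temperature series is generated beyond the panel
window by the lag span so that every estimation row has its lags defined.
Deaths can optionally be drawn as Poisson counts around `rate × pop`; the
default generates the continuous rate directly, matching the linear
estimator.

What the generator does *not* emulate: spatial correlation of weather
between neighbouring counties, trends in the seasonal cycle, outcome
autocorrelation beyond the fixed effects, or realistic US geography and
demography. Passing tests therefore certify the estimators' algebra and
sampling properties under the stated generating process, not the
substantive conclusions one would draw from any real dataset.

Station networks for the interpolation stage place stations uniformly in a
bounding box and evaluate known constant or planar fields, so
inverse-distance-weighted (IDW) estimates can be compared with the exact
field value. IDW uses haversine distances (appropriate at continental
scale), power 2, and all stations by default; a station coincident with the
target returns its value exactly, and conflicting coincident stations are
an error. Monthly aggregation averages daily interpolated values for
temperature and — deliberately — also for precipitation by default, with a
`sum` option since monthly precipitation totals are the more common
convention elsewhere.

## Numerical choices and edge cases

* Demeaning tolerance `1e-10` relative to column scale, 2,000 sweeps
  maximum; non-convergence is an error reporting the last delta.
* A regressor constant within fixed-effect cells demeans to numerical
  zero; because `qr()` judges rank relative to each column's own norm,
  such columns are detected separately (demeaned norm below `1e-8` of the
  original) and named in the error.
* AIC is undefined (an error, not −∞) when the residual sum is at
  floating-point roundoff of the response scale, i.e. an exact fit.
* AIC ties break toward fewer parameters, then listing order.
* Candidate bases that fail to fit are excluded from selection with a
  warning, never silently.
* All generators are deterministic functions of their seed; the pipeline
  manifest records seed, package version and a configuration hash so a run
  can be reproduced bit for bit.

## Worked example sizes

The test-suite studies use: 50 random panels (≤2,000 rows) for the
estimator-vs-oracle equivalence; 500 replicates of the default
100 × 10-year confounded panel for bias and CI coverage (coverage lands
near 94%); 200 replicates of a 40-county panel for the lead-placebo
centering; 100 replicates each of 57,600-row spline-truth and linear-truth
panels for AIC selection rates; and a 200 × 10 bootstrap-by-model ensemble
for the projection structure. These sizes were chosen so each study's
Monte Carlo error is small relative to the effect it measures.
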