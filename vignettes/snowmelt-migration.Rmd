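---
title: "Methods: snowmelt tracking and step selection in snowtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snowmelt tracking and step selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowtrack)
```

This vignette is the package's own account of its models, the choices
behind them, and what the synthetic validation does and does not show.

## The two questions and their models

Arctic-breeding raptors migrate north in spring across a landscape
whose snow cover retreats poleward over a few weeks. Two distinct
behavioural hypotheses are modelled separately.

**Timing: tracking the melt front.** If a migrant times its movement
to the front, then at any location it uses, snow should be present
shortly before its visit and gone shortly after. We therefore hold
each used location fixed and extract the environmental value at lag
days $\tau = -10, \dots, +10$ around the visit (`lag_extract()`,
`lag_table()`). Day length is *recomputed* at the shifted date (the
only reading under which a day-length trend over the window is
meaningful; the alternative — fixed-date day length — would be
constant by construction and is not offered). Each variable is
modelled as

$$\text{value}_{ij\tau} = \alpha + \beta\,\tau + u_i + v_{ij} +
\varepsilon_{ij\tau},$$

with random intercepts for individual $u_i$ and year-within-individual
$v_{ij}$, gaussian by maximum likelihood for temperature, day length
and NDVI, binomial by the Laplace approximation for binary snow
(`fit_lag_model()`, fitted with lme4). Only random intercepts are
used: the grouping structure is specified, random slopes are not.
With fewer than two individuals the model falls back to a
fixed-effects fit with a warning; a constant response returns a
flagged degenerate zero-slope fit rather than an optimiser failure.

**Choice: step selection against snow.** Movement is discretised into
steps of 1, 3 or 5 days. Each observed step is compared with $K = 10$
alternatives sharing its start fix and date, and the decision is
modelled by the exact conditional (stratum-softmax) likelihood

$$\ell(\beta) = \sum_s \left[\beta^\top x_{\text{chosen},s} -
\log \sum_{j=0}^{K} \exp(\beta^\top x_{j,s})\right],$$

maximised by Newton–Raphson with the analytic gradient and the
observed information (`fit_clogit()`). Conditioning removes anything
constant within a stratum, so no intercept is fitted, and predictors
without within-stratum variation are dropped with a warning (their
coefficients are not identifiable). Numerical contract: fixed start
at $\beta = 0$, convergence when the gradient norm falls below 1e-8,
at most 50 iterations; a coefficient path escaping beyond $|\beta| >
20$ is diagnosed as complete separation and reported as an error
naming the predictor, because the conditional likelihood then has no
finite maximum.

The reference analysis in the field fits this model with a
stratum-within-individual random effect (a mixed conditional logistic
model). `snowtrack` deliberately uses the exact *fixed-effects*
conditional likelihood and offers individual-level cluster-robust
(sandwich) standard errors (`cluster = "individual"`) as the stand-in
for that random effect. The inferences the analysis rests on —
coefficient signs and $\Delta$AIC between nested models on identical
strata — are supported by the fixed-effects likelihood; the
approximation is stated rather than hidden, and the robust/naive SE
contrast is available to gauge how much within-individual dependence
matters.

**Model comparison.** `compare_models()` computes
$\Delta\text{AIC}_i = \text{AIC}_i - \min_j \text{AIC}_j$ and Akaike
weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$. Models are
flagged as "different" only when $\Delta\text{AIC} > 2$ holds
*strictly*; fits on differing row counts are refused. Collinearity
among candidate predictors is screened by pairwise Pearson
correlation with a 0.7 flag threshold (`screen_collinearity()`);
zero-variance predictors are reported separately because their
correlation is undefined.

## Track processing

**Quality filter.** Argos location classes are ordered
3 > 2 > 1 > 0 > A > B > Z; classes below 2 (positional error above
roughly 500 m) are removed by default, GPS fixes are never filtered.
Individual-years left with fewer than 3 fixes are dropped with a
warning, and every removal is counted in the accounting log.

**Burst resampling.** `resample_steps()` implements a greedy forward
scan: fixes closer to the current anchor than
$\text{step} - \text{tol}$ are removed, the first fix inside
$[\text{step} - \text{tol},\ \text{step} + \text{tol}]$ extends the
burst, and an overshoot past the upper bound closes the burst and
starts a new one. The tolerance (default 10% of the step length) is
needed because real sampling is irregular; the rule is idempotent, so
re-resampling a resampled track is a no-op. Bursts keep at least two
fixes; single-fix bursts carry no step and are discarded.

**Geometry.** Step lengths are haversine distances on a sphere of
radius 6371 km; at raster resolution the sub-percent difference from
an ellipsoid is irrelevant, and the tests hold the haversine to within
0.5% of a geodesic reference for sub-500-km steps at study latitudes.
Headings are initial bearings; turn angles are signed smallest
differences between consecutive headings in $(-180, 180]$. Coincident
consecutive fixes yield a zero-length step that carries the previous
heading and is flagged.

**Spring segmentation.** First passage time (FPT) is the time for the
trajectory to first leave a circle of given radius (default 100 km)
centred on a fix. The convention is *forward-only* — the search runs
forward from each fix, with the crossing time interpolated linearly in
distance between the bracketing fixes — which keeps the contract
simple and testable against closed forms (uniform motion gives
exactly radius/speed). The migration segment is the longest
contiguous run of fixes with FPT below a threshold, clipped to a
spring window (March–June by default). The default threshold is the
density valley between the two largest modes of log-FPT (travelling
versus stationary); both radius and threshold are overridable, since
no universal values exist and the right choice depends on tag
programming and species.

## Environmental annotation

Raster series (`env_series`) are daily stacks on regular lon/lat
grids; snow is strictly binary, the rest continuous. Lookup is
nearest-cell with ties broken toward the lower grid index — bilinear
interpolation is deliberately avoided because the headline variable is
binary, and the continuous variables use the same rule for
consistency. Points beyond half a cell outside the grid, or outside
the covered dates, annotate as missing with a logged count. The
synthetic wind and temperature fields are daily; analyses here
operate at one-day steps and coarser, so sub-daily weather structure
is out of scope.

Day length uses the CBM declination/hour-angle formula. The package
default defines daylight by the sun's centre crossing the horizon
(depression angle 0), which makes day length exactly antisymmetric
across the equator; `horizon_offset_deg = 0.8333` reproduces the
common upper-limb-plus-refraction convention, and the two differ by
at most about a quarter hour at study latitudes. Wind support is
$u\sin h + v\cos h$ and crosswind $u\cos h - v\sin h$ for heading $h$
clockwise from north, so support² + crosswind² = u² + v² exactly;
heading is the step's initial bearing, and in strata each endpoint
uses its *own* start-to-endpoint bearing (the alternative reading —
re-using the chosen step's bearing for all endpoints — would make the
wind covariates stratum-constant and drop out of the conditional
likelihood, which is a further reason to prefer the per-endpoint
convention). Wind covariates are computed only at the one-day scale;
at 3- and 5-day steps a single day's wind is not representative of
the step.

## Building strata

The step-length kernel is exponential with the maximum-likelihood
rate $1/\overline{d}$ fitted to observed step lengths, pooled across
the individuals of a species (a per-individual fit is available).
Turn angles are resampled empirically with replacement rather than
fitted parametrically — no distributional form is imposed where none
is needed. Alternatives take the previous step's heading plus an
empirical turn draw and an exponential distance; the first step of a
burst has no previous heading and is skipped (counted). Alternatives
landing off the grid are redrawn up to 100 times rather than clipped,
which preserves the kernel away from the edges; a stratum that cannot
be completed is dropped and counted.

## UHC validation

`uhc_validate()` draws $\beta^* \sim N(\hat\beta, \hat V)$, weights
each held-out stratum's endpoints by $\exp(\beta^{*\top} x)$, samples
one "predicted used" endpoint per stratum, and accumulates the
covariate distribution; the envelope is the pointwise 2.5–97.5%
band over resamples (default 1000), and coverage is the fraction of
the grid where the observed used distribution lies inside it.
Continuous covariates use a Gaussian kernel density with Silverman's
bandwidth on a 100-point grid, renormalised to unit trapezoid
integral; binary snow uses the two-cell proportion vector. The
train/test split is by individual (default 30% of individuals held
out) because strata within an individual are dependent; splitting
strata at random would leak information and overstate calibration.

## The synthetic study system

The generator exists so that every stage of the pipeline can be
validated against known ground truth; its defaults describe one
plausible low-Arctic spring.

* **Snow front.** The melt front latitude moves north linearly,
  $L(t) = L_0 + vt$ (defaults 57°N, 0.2°/day over March–June on a
  10°x20°, 0.25°-cell grid). A cell's snow probability is
  $\mathrm{logit}^{-1}(k\,(\text{lat} - L(t)))$, thresholded at 0.5,
  so each cell's melt timing traces a sigmoid in time — slow far from
  the front, fastest as the front passes, slow at the end — while the
  *emitted* variable is strictly binary, matching the analysed
  product, in which interpolation has discarded fractional cover.
  Deterministically melted cells never re-freeze (this is what makes
  melt monotonicity a testable invariant); a per-cell Bernoulli flip
  probability can re-introduce observation-like flicker.
* **Continuous fields.** Temperature and NDVI are affine in day and
  latitude (defaults: +0.25 °C/day, −0.8 °C/° lat; +0.01 NDVI/day,
  −0.02 NDVI/° lat; NDVI clipped to [−1, 1]) with optional Gaussian
  noise; wind is a mean vector plus a smooth random-phase harmonic
  field redrawn daily.
* **Agents.** Each decision draws K candidate endpoints (exponential
  distances, mean 80 km/day; wrapped-normal bearings, SD 40°, centred
  on the direction to an attraction point) and selects one with
  probability $\propto \exp(\beta^\top x)$. The attraction point sits
  at $L(t) + \delta$ with $\delta$ = +3° (AHEAD, in snow), 0
  (ON_FRONT) or −3° (BEHIND, snow-free) — the simplest mechanism that
  reproduces the three front-position phenotypes (mostly-snow /
  mixed / mostly-bare occupancy). The generator records every
  candidate set with its covariates, giving ground-truth strata.

**What the synthetic data do not emulate:** cloud gaps and polar
darkness in the snow product, Argos positional error (classes are
labels only), orography and coastlines, sub-daily weather, and any
re-freezing in the deterministic mode. Passing the validation
therefore demonstrates the correctness of the statistical machinery
and the internal consistency of the pipeline on clean data — not
robustness to the observation artefacts of real satellite or Argos
data.

Two further honest caveats. First, occupancy percentages measured at
the nearest-cell scale are more extreme than neighbourhood-scale
figures (an agent sitting one cell north of the front reads 100%
snow); `occupied_snow_fraction()` exposes a neighbourhood radius
rather than fixing one, because the appropriate scale is a choice,
and only the AHEAD > ON_FRONT > BEHIND *ordering* is asserted in
validation. Second, the ON_FRONT demo shows a positive fitted snow
coefficient even when the true step-level snow preference is zero:
the pull toward the (snowy, northern) front is a movement bias absent
from the covariate set, and the SSF absorbs it into the snow term.
This confound is intentional — it is precisely what UHC validation
and drop-one AIC comparison are there to expose.

## Validation study sizes

The simulation studies behind the package's validation are sized to
run comfortably on a single CPU: fitter-versus-grid agreement on 50
strata (grid spacing 0.001); bias and 95% CI coverage over 100
datasets of 100 strata at $\beta_\text{snow} = -1.5$; type-I error
over 200 null datasets; lag-slope recovery over 50 individual-year
series of 21 lags (true slope 0.30); binomial lag slopes and
phenotype ordering on a 45-day, 0.25° landscape with 8–20 agents per
mode; and the UHC contrast over 50 paired replicates (150 training
and 250 test strata, 300 resamples, true $\beta_\text{snow} = -2$
versus a snow-omitted fit). Larger sizes change none of the
qualitative outcomes, only the Monte-Carlo error.

## Known limitations

* The conditional-logit model is fixed-effects; genuinely strong
  stratum-level heterogeneity would require the mixed model the
  robust SEs only approximate.
* The movement kernel of the SSF (exponential distance, empirical
  turns) is not estimated jointly with selection (no integrated-SSF
  likelihood), matching the two-stage design it emulates.
* FPT segmentation parameters are data-dependent; the bimodality
  default is a heuristic and should be inspected per dataset.
* Rasters must share a regular lon/lat grid; there is no reprojection.
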