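# snowtrack

Spring migration of Arctic-breeding raptors against the receding snow
line: do migrants time their northward movement to the progression of
snowmelt, and do they avoid snow-covered ground when choosing each
step?

`snowtrack` is an R package for answering both questions from
Movebank-style tracking data and daily environmental raster series
(binary snow cover, temperature, NDVI, wind U/V), and for validating
the whole pipeline end-to-end on synthetic tracks whose selection
behaviour is known exactly.

## What it computes

**Environmental lag models ("do they follow the melt?").** For every
used location the environmental value is extracted at that fixed place
from 10 days in the past to 10 days in the future. If birds ride the
melt front, snow cover declines across that window (they sit just
where snow is about to disappear), day length, temperature and NDVI
rise. Each variable is modelled as

    value ~ day + (1 | individual) + (1 | individual:year)

with a gaussian family (ML) for continuous variables and a binomial
family (Laplace) for snow, via lme4. Evidence is summarised by AIC
against the intercept-only model, with Akaike weights
`w_i = exp(-ΔAIC_i/2) / Σ_j exp(-ΔAIC_j/2)` and models treated as
different only when ΔAIC > 2 (strictly).

**Step-selection functions ("do they avoid snow?").** Tracks are
resampled into bursts at 1-, 3- and 5-day steps; each observed step is
matched with K = 10 alternative endpoints drawn from an exponential
distance kernel and the empirical turn-angle distribution. Each
stratum (1 chosen + K alternatives, annotated with snow and — at the
one-day scale — wind support and crosswind) enters the exact
conditional logistic likelihood

    ℓ(β) = Σ_s [ βᵀx_chosen,s − log Σ_j exp(βᵀx_j,s) ]

maximised by Newton–Raphson with analytic gradient and Hessian;
cluster-robust (by individual) standard errors are available. Fitted
models are validated with used-habitat-calibration (UHC) plots:
the observed covariate distribution at chosen endpoints is compared to
the envelope obtained by resampling β* ~ N(β̂, V̂) and redrawing
"predicted used" endpoints on held-out individuals.

Supporting machinery: Argos-class quality filtering (classes below 2
removed, GPS untouched), first-passage-time segmentation of the spring
migration, astronomical day length (CBM formula), wind
support/crosswind decomposition, and a synthetic-data module — a
northward-receding sigmoidal melt front, smooth temperature/NDVI/wind
fields, and agents that choose steps by a stratum softmax in known
coefficients while staying ahead of, on, or behind the front.

## Worked example

Simulate a landscape and twelve agents that ride the melt front, then
run the full pipeline:

```r
library(snowtrack)

cfg     <- snow_front_config(dates = seq(as.Date("2016-03-01"),
                                         as.Date("2016-05-31"), by = "day"))
rasters <- c(list(snow = make_snow_series(cfg)), make_env_fields(cfg))
agents  <- agent_config(n_individuals = 12, n_steps = 60,
                        coupling = "ON_FRONT",
                        beta = c(snow = 0, wind_support = 0.05), seed = 7)
sim <- simulate_agents(agents, rasters, cfg)

f <- tempfile(fileext = ".csv")
write.csv(sim$tracks, f, row.names = FALSE)
res <- run_pipeline(
  pipeline_config(tracks_path = f, out_dir = tempfile(), species = "demo",
                  step_scales = c(1, 3), run_segmentation = FALSE, seed = 1),
  series_map = rasters)

res$lag_fits$snow
#> Lag model: snow ~ day (binomial), 14712 rows, 12 individuals
#>   day slope -0.4609 (SE 0.0073), logLik -4818.0, AIC 9644.1

summary(res$ssf_fits$scale_1)
#>              Estimate Std. Error z value  Pr(>|z|)
#> snow         0.445380   0.104107  4.2781 1.885e-05 ***
#> wind_support 0.066664   0.041206  1.6178    0.1057
#> crosswind    0.044376   0.040828  1.0869    0.2771
#> logLik -1686.77   AIC 3379.54   strata 708
```

The strongly negative snow-versus-day slope says snow disappears from
used locations as the window moves from past to future — the agents
are indeed riding the melt. The wind-support coefficient recovers its
true value (0.05) within one standard error. The positive snow
coefficient, although the true step-level snow preference is zero, is
a deliberate feature of this scenario: the agents' pull toward the
(snowier, northern) front is a movement bias the three-covariate model
does not contain, and the SSF absorbs it into the snow term. The UHC
validation and the drop-one AIC table (`res$ssf_comparisons$scale_1`)
are the tools for catching exactly this kind of mis-specification.

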