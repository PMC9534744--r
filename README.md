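# chronex

Chronicle-based local-extinction analysis for range-contracting species.

Historical chronicles — gazetteer records, physical remains, rescue
reports — are one of the few data sources that track where a species
disappeared over centuries. `chronex` implements a complete analysis
pipeline for such data, built around the workflow used to study the
local extinction of the Chinese pangolin (*Manis pentadactyla*) across
mainland China between 1700 and 2000 AD:

1. **Fate encoding** — dated occurrence records are gridded into
   0.5-degree cells and ten 30-year periods. A cell's last detection
   period is coded 0 (presence) and, if the species is never detected
   there again, the following period is coded 1 (absence): one
   presence/absence pair per observed local-extinction event.
2. **Additive logistic model** — a penalized-spline binomial GAM relates
   the 0/1 fate to period-averaged covariates (human population density
   and count, cropland, grazing, an ice-core temperature proxy, regional
   temperature) plus a tensor-product spatial smooth:
   `logit P(fate = 1) = s(temp) + s(popc) + ... + te(lon, lat)`.
   A collinearity screen (|r| > .95, single-term adjusted R²/AIC
   comparison) mirrors the exclusion of the China-wide population total,
   which tracks the temperature proxy at r = .98.
3. **Extinction-record screening** — recent historical records
   (1970–2000) that fall outside the current range polygon *and* more
   than 50 km from every extant record are extinction occurrences; they
   are spatially rarefied to 10 km and checked with Ripley's K.
4. **Maximum-entropy risk model** — an L1-penalized Gibbs distribution
   over background cells (linear, quadratic, and decile-knot hinge
   features) is fitted to the extinction records, with the
   pre-experiment zero-contribution screen, the |r| > .7 correlation
   filter, 100 replicate subsample fits, and logistic output
   `p = q·e^H / (1 + q·e^H)`.
5. **Risk classification** — the averaged surface is thresholded at
   maximum sensitivity + specificity and the at-risk probabilities are
   split into low/moderate/high classes by exact Fisher–Jenks natural
   breaks; extant sites are tallied per class and region.
6. **PCA attribution** — correlation-matrix PCA of the environmental
   values at extinction records compares climatic against anthropogenic
   variability.

A synthetic-data generator with known ground truth (logistic per-period
extinction hazard driven by a rising, fluctuating temperature proxy and
growing population) makes every stage testable end to end without any
external download.

## Worked example

```r
library(chronex)

params <- simulation_params(seed = 42)        # the default study conditions
stack  <- simulate_covariates(params)
sim    <- simulate_chronicles(params, stack)
fates  <- encode_fates(sim$occurrences, sim$grid, period_spec(1700, 30, 10))
fates  <- uncensored_rows(attach_covariates(fates, stack, 10))
nrow(fates)
#> [1] 926

fit <- fit_extinction_gam(fates, c("temperature", "popc", "cropland"))
fit
#> Additive logistic extinction model (penalized splines)
#>   n = 926 fate rows; deviance explained = 0.030; adjusted R2 = 0.022
#>   s(temperature)         edf  1.00  Chi.sq    35.55  p 0 ***
#>   s(popc)                edf  1.00  Chi.sq     0.07  p 0.7864
#>   s(cropland)            edf  1.00  Chi.sq     0.73  p 0.3921
#>   te(lon,lat)            edf  3.00  Chi.sq     8.39  p 0.0386 *
```

The 926 rows are the 463 observed extinction events of this simulation,
each contributing one presence and one absence row. The temperature
smooth is strongly significant and its partial effect rises
monotonically (−1.25 to +1.25 on the logit scale across the proxy
range), recovering the positive temperature effect the generator planted
(`beta_temp = 1`); the per-cell population count carries no independent
signal here because the hazard's population term is weaker and collinear
with the trend.

The decision-support operations behave the same way on small inputs:

```r
max_sss_threshold(pres = c(0.8, 0.6), bg = c(0.7, 0.2))
#> max-SSS threshold 0.6000 (sensitivity 1.000 + specificity 0.500 = 1.500)
jenks_breaks(c(0.25, 0.30, 0.42, 0.55, 0.61), k = 3)
#> [1] 0.30 0.42 0.61
```

The whole pipeline, chained and written to plain-text artifacts (CSV,
ESRI ASCII grids, GeoJSON, JSON reports):

```r
cfg <- chronex_config(background_n = 1000, replicates = 20, rng_seed = 7)
run_pipeline(cfg, "out/", verbose = TRUE)
```

or from a shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli.R", package = "chronex"))')" \
  all --seed 7 --out out/
```

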