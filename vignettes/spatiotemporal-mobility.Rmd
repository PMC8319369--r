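---
title: "Modelling seasonal subnational mobility with stmobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal subnational mobility with stmobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmobility)
```

## The data world

The package analyses monthly origin–destination mobility at the level of
administrative units — in the bundled fixture, Kenya's 47 counties grouped
into 8 former provinces — as observed through a differentially-private
release of weekly flow counts. Three properties of that release shape
everything downstream:

* every weekly count carries zero-mean Laplace noise of scale `1/0.66`
  (privacy budget ε = 0.66 per metric, with a small δ carried as metadata);
* noisy counts strictly below 100 are suppressed before publication
  ("lower than 100" is read as strict: a noisy count of exactly 100 is
  retained);
* only the surviving weeks are aggregated to months.

Noisy counts are kept real-valued through suppression and aggregation; the
release never states a rounding step, so none is applied.

The outcome of interest is the monthly **mobility change ratio**: a
county's total outward flow (within-county, domestic and international
destinations all included, since within-county travel dominates the total)
divided by the same county's January flow of that year. January rows are
emitted with ratio exactly 1, which makes a complete two-year panel
47 × 24 = 1128 observations; this matches the convention of counting the
baseline month in the analysis dataset. An equivalent reading indexes the
ratio over February–December only (47 × 22 = 1034 rows); the package
defaults to the January-inclusive panel and exposes
`include_january = FALSE` in `build_design()` for the other reading.
County-years with a missing or non-positive baseline are excluded and
reported, never silently dropped or imputed.

## The model

On the log scale (ratios are positive, and the log transformation makes
the Gaussian error assumption tenable),

$$\log(y_{it}) = \beta_0 + A_i + B_t + C_{it} + X_{it}'\beta + \epsilon_{it}$$

* `A_i` — BYM2 spatial effect: `A = (sqrt(φ) u* + sqrt(1-φ) v) / sqrt(τ_A)`
  with `u*` the intrinsic CAR (ICAR) effect on the contiguity graph, scaled
  so its generalized marginal variance is one, and `v` iid standard Normal.
  φ ∈ [0,1] mixes structure against noise; τ_A is the single marginal
  precision. The scaling factor is the geometric mean of the diagonal of
  the blockwise pseudo-inverse of the ICAR structure matrix; sum-to-zero
  constraints and scaling are applied per connected component, so
  disconnected graphs (island regions) are handled without special casing,
  and singleton components carry no structured effect.
* `B_t` — stationary AR1 over the 24 consecutive months, coefficient ρ and
  innovation precision τ_B (stationary variance `1/(τ_B (1-ρ²))`). The time
  index runs continuously across the year boundary; a year-break restart is
  not modelled.
* `C_it` — space–time interaction. The package implements the simplest
  (type I) structure: iid Gaussian per county-month with precision τ_C.
  The interaction types that inherit spatial or temporal dependence
  (II–IV) are deliberately out of scope for the first release; type I is
  the minimal faithful reading of "an interaction between the spatial and
  temporal components".
* `ε_it` — Gaussian observation noise with precision τ_ε.

### Priors

None of the priors are dictated by the reported analysis, so the package
makes conventional, fully exposed choices (`model_spec(priors = ...)`):

* fixed effects: Normal(0, 10²);
* every standard deviation (noise, spatial, temporal, interaction):
  penalized-complexity (exponential-on-sd) prior with P(sd > 1) = 0.01;
* BYM2 mixing φ: Beta(1, log 3 / log 2), calibrated so P(φ < 0.5) = 2/3.
  The exact PC prior for φ requires graph-eigenvalue KLD computations; the
  calibrated Beta keeps the same prior mass statement with far less
  machinery, and the package treats that as an acceptable design trade;
* AR1 ρ: standard Normal on the Fisher transform atanh(ρ), symmetric, so
  P(ρ > 0) = 1/2.

### Inference

Inference is by Markov chain Monte Carlo rather than a nested-Laplace
approximation, because every Gibbs block can then be verified against
closed-form Gaussian oracles at desk scale. One iteration:

1. conjugate precision-solve draws for β, `u*`, `v`, `B` and `C`. The
   sum-to-zero constraint on `u*` (per component) is re-imposed at every
   draw by conditioning-by-kriging, which is exact for Gaussian vectors;
2. exact translation sweeps: for each fixed-effect column, a Gibbs draw of
   a shift along the likelihood-invariant direction it shares with `v`
   (region-constant columns), `B` (time-constant columns) and `C` (all
   columns). Without these, the intercept and the static covariates mix
   very slowly because they are confounded with the random-effect levels;
   the sweeps leave the posterior unchanged (verified against the plain
   sampler run 10× longer) and make single chains of a few thousand
   iterations usable;
3. random-walk Metropolis on log τ_ε, log τ_A, logit φ, log τ_B,
   atanh ρ and log τ_C, with step sizes adapted toward 44% acceptance
   during burn-in only (then frozen, so post-burn-in chains are valid and
   bit-reproducible given the seed).

Proposals for ρ live on the Fisher-z scale, so values outside (−1, 1)
cannot occur; non-finite log-densities abort the chain with the offending
state reported. Convergence is screened by split-chain potential scale
reduction factors; the recovery harness excludes (and counts) replicates
with split-Rhat > 1.05 on any fixed effect.

### A known non-identifiability, on purpose

With a type-I interaction under a Gaussian likelihood, `C_it + ε_it` is the
sum of two iid effects per cell: the data identify only the sum of their
variances, and the τ_ε/τ_C split is resolved by the priors alone. Fits on
real-shaped data therefore often show high split-Rhat for τ_ε while every
fixed effect is stable — the summaries expose this rather than hiding it.
Fixed-effect recovery (the quantity the analysis reports) is unaffected,
which is exactly what the recovery experiment measures. DIC's pD can be
large for the same reason: the cell-level interaction is counted as
effective parameters.

## The synthetic generator

`simulate_covariates()` draws static covariates inside the observed ranges
of the real covariate sources (urban share 0.001–0.947, poverty
0.099–0.917, no-primary-education share 0.032–0.17, accessibility
4.37–380.66 minutes) and builds monthly series: a county-specific seasonal
temperature sinusoid clamped to 14.7–28.8 °C; aridity, precipitation and
EVI as affine functions of temperature plus noise (so the collinearity
screen faces the structure it exists for, with |r| ≈ 0.9 at defaults);
night-time lights tracking urbanicity only loosely (r ≈ 0.4, below the
screen threshold, as in the real covariate set); and a fixed national
school-holiday calendar (April, August, November–December term breaks; 0–31
days per month) independent of temperature.

`synthetic_truth()` defaults the generating parameters to the magnitudes
reported for the Kenya analysis (e.g. education 5.337, poverty −1.098,
temperature −0.052; τ_ε = 3.838, τ_A = 12.875, φ = 0.209, τ_B ≈ 1.88e4,
ρ = −0.229). The reported table lists no interaction precision, so the
default τ_C = 10 places the interaction sd (≈0.32) below the noise sd
(≈0.51) — an interaction smaller than noise, chosen once and not revisited.

`simulate_panel()` turns generated log-ratios into flow records: January
outward flow is a county-level base (log-normal spread around
`base_flow`), other months scale it by the generated ratio, totals are
split into within-county / domestic / international records (defaults
0.65/0.25/0.10, within-county dominant) with gravity-style destination
allocation over synthetic coordinates and a fixed 10-country international
list weighted toward East Africa, and months are disaggregated into weeks
proportionally to week length with largest-remainder rounding to whole
users. The returned truth change series is computed from the realized
(integer) flows, so the no-privacy round trip through the metrics stage is
exact; the intended model-equation ratios are returned alongside.

What the generator does **not** emulate: the real OD microstructure
(gravity on synthetic coordinates is a documented stand-in), reporting
biases of opt-in location data, and any COVID-era regime change. A green
test establishes that the pipeline recovers the parameters of *this*
generating process through *this* release mechanism — not that the real
mobility data would yield the published coefficients, which require the
proprietary source.

### Recovery experiments and the January rows

`recovery_experiment()` simulates outcomes directly from the model equation
over the full 47 × 24 grid and refits. It does not re-baseline through the
flows pipeline, for a structural reason: the change ratio divides out each
county's January level, so re-baselined outcomes cancel `A_i` and every
static covariate by construction. The January-ratio identity belongs to the
metrics world (where January rows are emitted with ratio 1); model fits
include those rows by default to match the 1128-observation convention, and
`include_january = FALSE` is available. At defaults, 20 replicates at full
design size give ≈90% pooled coverage of the generating fixed effects and
100% sign agreement for strongly identified effects.

## Numerical choices and degenerate inputs

* The BYM2 scaling factor uses eigendecomposition pseudo-inverses per
  component; all-singleton graphs are an error (no structured variation is
  definable).
* `compute_change_ratios()` sets baseline-month ratios to exactly 1 (not
  `x/x`, avoiding float noise) and excludes-and-reports county-years with
  non-positive baselines.
* Suppression keeps counts `>= threshold` (strict reading of "lower
  than"); a week belongs to the month containing its start date, with
  52 fixed-length study weeks per year (week 52 absorbs the year's tail
  days).
* Validation scores on the ratio scale by default (the scale on which MAE
  values are conventionally reported for this analysis); log-scale scoring
  and the 1 − SSE/SST pseudo-R² variant are flags. Constant vectors make
  the correlation-based pseudo-R² undefined: it is reported as missing with
  a warning, never as 0 or 1.
* All generators, the release mechanism and the sampler are pure functions
  of (configuration, seed).

## Limitations

Type II–IV interactions and INLA-style marginal-likelihood computation are
not implemented. The bundled Kenya contiguity list is a hand-curated
approximation (queen rule) shipped for testing and demonstration; analyses
of real geographies should supply their own edge list. The covariate
module consumes already-modelled gridded surfaces via zonal statistics; it
does not reproduce the upstream education/poverty/accessibility models or
read native raster formats.
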