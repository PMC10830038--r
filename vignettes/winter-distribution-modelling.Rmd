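---
title: "Modelling winter-season distribution from raptor telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter-season distribution from raptor telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raptorwinter)
```

## The problem

Wintering populations of large raptors such as golden eagles mix
year-round resident territory holders, non-territorial resident
"floaters", and long-distance migrants of all age classes. Conservation
planning built only on nesting-habitat models misses the birds that are
not tied to local breeding territories. `raptorwinter` implements a
complete, reproducible pipeline that turns raw GPS/Argos telemetry into a
winter-season map of *relative intensity of use* — a per-cell value on
[0, 1] proportional to the expected density of use locations — and
evaluates and compares that map. Because real telemetry of this kind is
not freely distributable, the package ships a synthetic-data generator
with known ground truth; every stage of the pipeline is validated against
that truth.

## Pipeline overview

The stages mirror standard practice for telemetry-based distribution
modelling, in this order:

1. **Location proofing.** Argos fixes are kept only in location classes
   3/2/1 (error radii under 250 m, 250-500 m, 500-1500 m). Out-and-back
   *spikes* are removed when the interior turn angle is below 15 degrees
   with both legs over 2,500 m, or below 25 degrees with both legs over
   5,000 m, re-applied until stable. A greedy forward velocity filter
   removes fixes implying sustained speeds above a threshold (candidates
   20, 27.8 and 40 m/s; default 27.8, the middle candidate — a
   configurable, reproducible stand-in for per-track visual selection).
   Locations are then standardized to at most one per UTC clock-hour
   (clock-hours rather than rolling windows: deterministic and
   timezone-free).
2. **Season and time of day.** Winter is December-February; summer
   (June-August) is kept separately for home-range estimation. Winter
   fixes are retained only between one hour after sunrise and one hour
   before sunset, computed per fix with the NOAA solar method (zenith
   90.833 degrees).
3. **Life-history classification** (below), which also removes
   territory-associated winter locations.
4. **Behavioural state.** Tracking bouts of at least 28 days with no gap
   over 48 hours are segmented; residence-in-space-and-time (RST)
   classification separates sedentary from transiting fixes at a 30-km
   radius (candidates 6-30 km; the radius is a parameter).
5. **Temporal thinning** to two locations per individual per day — one
   before and one after local solar noon, at least one hour apart, chosen
   at random under a caller-supplied seed. Solar noon is computed per fix
   from longitude rather than using a study-wide constant; the seasonal
   mean at the study-area centroid (about 12:20 local standard time) is
   retained as a documentation cross-check in the test suite.
6. **Train/test split**, 75% / 25% by location.

Every filter only removes rows — coordinates and timestamps are never
altered — and returns a removal log so that input count equals output
count plus per-reason removals.

## Life-history classification

Individuals are classified by age (adult at 4+ biological years, with the
biological year starting in April), migratory status, and territory
status, producing the five observed combinations: Adult Migrant, Adult
Non-migrant Territory-holder, Adult Non-migrant Non-territorial
(floater), Non-adult Non-migrant, Non-adult Migrant. The cascade:

1. Migrants — birds tagged north of 58.25 N or whose summer 95% KDE
   centroid lies north of it — keep all study-area winter fixes.
2. Nestling-tagged birds lose fixes that are both within one year of
   tagging and within 3.2 km of the natal site (a territory-core
   radius). Unknown-natal first-year birds whose summer and winter
   ranges overlap and are both under 200 km² are removed outright.
3. Two-to-three-year-olds not tagged as nestlings keep all winter fixes.
4. Adults whose summer fixes all lie more than 16 km outside the study
   area are non-territorial; near-boundary adults lose winter fixes
   inside their summer range; adults with inadequate summer data (fewer
   than 25 locations or under 30 days) are removed.
5. Remaining adults are territory holders when the summer 95% KDE is
   under 200 km² (their winter fixes inside the governing summer KDE are
   removed), floaters otherwise.

Home ranges use a bivariate normal-kernel density with per-axis bandwidth
0.7 times the ad hoc reference bandwidth `sigma * n^(-1/6)`. We read the
"proportion of 0.7" as a bandwidth multiplier — the standard meaning of
an `href` proportion in home-range software — rather than a rescaling of
the density level; the isopleth is the smallest-density region holding
95% of mass, evaluated on a 200 x 200 grid, with point-in-range tests by
bilinear density interpolation.

## The intensity model

The engine is a penalized maximum-entropy model, the presence-background
formulation equivalent to an inhomogeneous Poisson point process. With
features \(f(x)\) scaled to [0, 1] on the background sample, coefficients
\(\lambda\) maximize

\[
L(\lambda) \;=\; \frac{1}{n_p}\sum_{i \in \text{presence}} f(x_i)\cdot\lambda
\;-\; \log \frac{1}{n_b}\sum_{j \in \text{background}} e^{f(x_j)\cdot\lambda}
\;-\; \sum_k \beta_k |\lambda_k|,
\]

with per-feature penalties
\(\beta_k = m \times \beta_{\text{class}}(n_p) \times \mathrm{sd}(f_k)/\sqrt{n_p}\),
where \(m\) is the global regularization multiplier and
\(\beta_{\text{class}}\) the published MaxEnt class schedules
(linear/quadratic/product, categorical, threshold, hinge), interpolated
on presence sample size. Feature classes are linear, quadratic, pairwise
products, threshold indicators and hinge ramps with knots at background
quantiles, and class indicators for categorical covariates.

Numerics: the objective is concave; optimization is cyclic
coordinate-wise proximal (soft-threshold) updates with the uniform
curvature bound 1/4 (the variance of a [0, 1]-bounded feature never
exceeds 1/4), which guarantees a monotonically non-decreasing penalized
objective. Convergence is declared when the relative objective change per
sweep falls below 1e-6 (tightened in equivalence tests). The
log-normalizer uses max-subtraction for stability. Projection computes
\(e^{f(x)\cdot\lambda}\) per cell with covariates clamped to the
background range (clamp counts are reported), then min-max scales to
[0, 1] over the clipped area. We use min-max-scaled raw output rather
than logistic or cumulative transforms because the mapped quantity is a
*relative* intensity on a 0-1 equal-interval scale; the choice only
recalibrates bin boundaries, not ranks.

Covariates enter after three reduction steps: (1) per base variable, the
best focal extent/statistic by the mean-ratio screen (mean at training
locations over mean at 10,000 random locations), requiring at least 20%
non-zero values at training locations — we adopt the "at least 20%
non-zero" reading of the ambiguous sparsity clause since it is the
reading that avoids pathologically sparse layers — with near-ties (5%
relative) resolved deterministically toward mid-ladder extents and
mean > sd > min > max; (2) iterative VIF filtering within variable
categories, removing the largest VIF while any is at least 4; (3)
refitting and dropping covariates with under 1% contribution, up to
three rounds. Percent contribution credits each positive penalized-gain
increment to the feature updated, aggregated to parent covariates
(products split equally between parents).

The regularization multiplier is tuned by repeated ~25% holdouts of the
training presences, scoring each candidate by the mean binned calibration
R² of the holdout against the refit (the background sample serving as
the area measure), with ties resolved to the larger, more general
multiplier. The tuning criterion of the cited optimization procedure is
not restated in our sources; mean cross-validated calibration R² is the
package's choice.

## Evaluation

The scaled surface is cut into ten equal-interval bins, `(0, 0.1]`
through `(0.9, 1]`, with zero in bin 1 (fixed intervals, not data-driven,
matching the 0-1 equal-interval map legend convention). Per bin we report
area, observed test-location counts, predicted counts
(`n_test` allocated proportionally to the bin's intensity mass — counts
are conserved by construction), the area-adjusted frequency
`AAF = relative frequency / relative area` (undefined for zero-area
bins, which are excluded from rank statistics; the identity
`sum(AAF * area share) = 1` holds exactly), the calibration R² (squared
Pearson correlation of observed and predicted counts), and the Boyce
index. The Boyce index is the Spearman rank correlation between AAF and
bin rank; tables in this literature report it **squared**, and the
squared convention is what reproduces the published worked example
(0.976 arises from a single adjacent rank swap: \(\rho = 0.9879\),
\(\rho^2 = 0.976\)); the raw correlation is retained as an attribute.
The AAF magnitude-of-difference is the top bin's AAF over the AAF of the
lowest-indexed occupied bin (the "bins 10:2" fallback when bin 1 is
empty), rounded to integer.

Geographic evaluation overlays 30 x 30- or 15 x 15-km grids: each raster
cell carries its intensity bin's AAF; a coarse cell's predicted count is
its mean AAF times its share of the modeling area times the total test
count. Predicted and observed counts over cells containing test data are
assigned rank-based quartiles (well-defined under ties — a constant
vector lands mid-ranking) and discordance is the absolute quartile
difference; cells without test data are flagged excluded rather than
forced into quartiles.

Surface comparison computes cell-wise Spearman correlation over the
mutual footprint and percent overlap of top-10%/top-20% *area* quantile
sets (fixed cell-count sets, ties broken by value then deterministic
cell order; the denominator is one top set — the two are equal-area).
Management summaries report each category's share of area and of top
quantile sets, and the observed:expected ratio (top-10% share over area
share, rounded to two decimals).

## The synthetic world

`simConfig()` defines the study system. Covariate fields are
Gaussian-filtered white noise (FFT convolution with circular boundary;
the wrap-around only touches a smoothing-length band at the grid edge),
standardized and shifted to mean 3, sd 1 so that mean-ratio screening
operates on positive values; within-category mixing of a shared field
induces realistic multicollinearity for the VIF stage, and a smooth
field cut at quantiles provides a categorical ecoregion layer. The true
intensity is \(\exp(\beta \cdot x)\), normalized to sum to one.

Movement is a two-state discrete-time walk: settlement centers sampled
with probability proportional to intensity to a configurable power, OU-
style wander within settlements, and straight directed transit legs
between distant settlements (labelled in truth). Migrants summer at
60-64 N; resident territory holders and nestling natal territories use
compact summer wander (95% KDE well under 200 km²) and floaters diffuse
wander (well over 200 km²). Argos error is isotropic displacement with
class-specific radii, and spike outliers are 10-km displacements injected
at a configurable rate. Group counts default to the deployment counts of
the study design the generator emulates (54/60/44/74/36); the defaults
use a 600 x 600-cell grid at the 120-m resolution of the covariate
products.

What the generator does **not** emulate: real autocorrelated
environment-driven movement, weather, energetics, Argos error geometry,
seasonal migration tracks between the summer and winter ranges, or the
67 real base environmental variables. Passing tests therefore demonstrate
that the pipeline's logic is correct and that parameters are recoverable
under a known generating model — not that any particular ecological
conclusion transfers to real data.

## Numerical choices and edge cases

- RST residence time and distance follow the track forward and backward
  to interpolated circle crossings (quadratic interpolation on the
  segment), so transit steps larger than the radius still accrue their
  within-circle path. Both are normalized by the bout maximum (they are
  non-negative; subtracting the minimum would erase the transit end of
  the scale), and residuals within 0.01 of zero are pooled with
  sedentary as the time-and-distance-intensive class.
- Focal windows are circular (cell centers strictly within the extent),
  so the 120-m window is the identity; edge cells use the truncated
  window, the behaviour a 20-km buffered analysis grid relies on.
- Thinning, splitting, background sampling and tuning all take explicit
  seeds; `withSeed()` isolates each draw from the global RNG stream, so
  reruns are bit-identical.
- Background points are drawn uniformly by rasterizing the union of
  20-km discs around training locations (FFT dilation) and jittering
  within sampled mask cells.
- Degenerate (constant) features are dropped at construction with a
  message; perfectly collinear covariates are removed first in VIF
  filtering with a warning; duplicate timestamps keep the first fix with
  a warning.

## Problem sizes

The test suite and the acceptance script run the full machinery at
deliberately small sizes — 60 x 60-cell worlds, around a dozen simulated
individuals, 1,000 training presences with 3,000 held-out evaluation
points, 4,000 background points, and ten replicate seeds for the
recovery study — sizes at which every stage completes in seconds while
the statistical checks (rank correlation above 0.9 against truth,
squared Boyce at or above 0.9, 95% label recovery) remain sharp. The
evaluation holdout is larger than the training set because the upper
intensity bins cover very little area; with only a few hundred test
points their AAFs are dominated by sampling noise even for the true
surface, which is the same reason the source literature evaluates on
thousands of withheld locations.

## Known limitations

- The raster container is deliberately minimal (regular grids, single
  CRS, nearest-cell extraction); it is not a general GIS replacement.
- The full Douglas Argos-filter is not re-implemented; only its stated
  spike and velocity rules are.
- The in-memory `runPipeline()` returns all stage artifacts and is
  deterministic given its configuration; file-based stage resumption is
  out of scope.
- Logistic/cloglog output transforms are not provided; the package's
  output scale is min-max-scaled raw intensity.
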