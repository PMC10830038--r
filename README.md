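# raptorwinter

Winter-season distribution modelling for GPS-tracked raptors.

Wintering golden eagle populations mix resident adult territory holders,
non-territorial resident adults ("floaters"), pre-breeding-age birds, and
long-distance migrants. Distribution models built from nesting data
describe only the first group; managers siting wind energy, planning
mitigation, or prioritizing habitat need a map of where *all* of these
birds concentrate in winter. `raptorwinter` is an R package for analysts
working with raptor telemetry who want to build and rigorously evaluate
such a map: it takes raw GPS/Argos fixes through a documented filtering
pipeline to sedentary daytime winter locations, classifies individuals
into life-history groups, engineers multi-scale environmental
covariates, fits a penalized maximum-entropy intensity model, and
evaluates the result with calibration and rank-based statistics.

## The model

The response is the **relative intensity of use**: a per-cell value on
[0, 1] proportional to the expected density of use locations. With
features `f(x)` (linear, quadratic, product, threshold, hinge, and
categorical indicators) scaled to [0, 1] on a background sample, the
coefficients maximize the L1-penalized maxent log-likelihood

    L(lambda) = mean_presence f(x).lambda
              - log mean_background exp(f(x).lambda)
              - sum_k beta_k |lambda_k|

— the presence-background formulation equivalent to an inhomogeneous
Poisson point process. Penalties follow the published MaxEnt class
schedules, `beta_k = m * beta_class(n) * sd(f_k)/sqrt(n)`, with the
global multiplier `m` tuned by repeated-holdout calibration R².
Optimization is coordinate-wise proximal ascent on the concave objective
(monotone by construction). Evaluation uses ten equal-interval intensity
bins: observed vs predicted counts (calibration R²), area-adjusted
frequencies (AAF), the Boyce index (rank correlation of AAF with bin
rank, reported squared per the field's tables), AAF magnitude ratios,
and grid quartile concordance. Because telemetry of this kind cannot be
redistributed, the package includes a synthetic-data generator with
known ground truth — smooth covariate fields, a log-linear intensity
surface, and movement tracks for all five life-history groups — so the
entire pipeline is testable end to end.

## Worked example

Evaluation arithmetic on the bundled worked-example AAF table (ten
intensity bins, adult-migrant column):

```r
library(raptorwinter)
tab <- lifeHistoryAAFTable()
boyceIndex(tab$adult_migrant)
#> [1] 0.9759045
#> attr(,"rho")
#> [1] 0.9878788
aafMagnitude(tab$nonadult_migrant)
#> [1] 162
```

The squared Boyce index 0.976 says the adult-migrant AAFs are perfectly
rank-ordered except one adjacent swap in the two lowest bins; the
magnitude 162 means the highest intensity bin held 162 times more
locations per unit area than the lowest occupied bin — strong,
well-calibrated selection.

A full synthetic run — simulate tracks for ten individuals across the
five life-history groups, filter, classify, select covariates, fit,
project, and score against the generating truth:

```r
cfg <- simConfig(nrow = 60, ncol = 60, smoothing_cells = 6,
                 n_base_per_category = 1, betas = c(wind_uplift_1 = 1.2),
                 groups = c(adult_migrant = 2, adult_res_territorial = 2,
                            adult_res_floater = 2, nonadult_resident = 2,
                            nonadult_migrant = 2), seed = 21)
res <- runPipeline(cfg, extents_m = c(120, 600),
                   statistics = c("mean", "sd"), classes = "linear",
                   n_background = 4000, n_random = 4000,
                   reg_multiplier = 1, seed = 2)
res$manifest[, c("stage", "n_in", "n_out")]
#>                stage  n_in n_out
#>          argos_class 42960 42960
#>                spike 42960 42187
#>             velocity 42187 42187
#>               hourly 42187 42187
#>       season_daytime 42187 27412
#>         life_history  6791  5555
#>     behavioral_state  5555  5354
#>             thinning  5354  1570
#>           train_test  1570  1178
#>  covariate_selection    16     6
round(res$contributions, 1)
#> vegetation_landcover_1_600m_sd        wind_uplift_1_600m_mean
#>                            1.1                           86.1
#>                      ecoregion
#>                           12.8
res$truth_spearman
#> [1] 0.962
```

The manifest shows each filtering stage's bookkeeping (e.g. 773 injected
spike outliers removed, night/off-season fixes dropped, two locations
retained per bird-day). The fitted surface rank-correlates with the true
intensity at rho = 0.96, and the covariate that actually generated the
point process (`wind_uplift_1`) dominates the percent contributions.

## Package layout

- `R/synthio.R` — synthetic world: covariate fields, true intensity,
  movement tracks with Argos error and injected outliers
- `R/telemetry.R` — proofing filters, solar season/daytime selection,
  RST behavioural states, thinning, train/test split
- `R/lifehistory.R` — KDE home ranges and the classification cascade
- `R/covariates.R` — focal statistics, mean-ratio scale selection, VIF
- `R/maxent.R` — features, penalized fit, tuning, contributions,
  pruning, background sampling, projection
- `R/evaluate.R`, `R/compare.R` — the evaluation and comparison suites
- `R/pipeline.R` — end-to-end orchestration with a stage manifest
- `vignettes/winter-distribution-modelling.Rmd` — the methods vignette
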