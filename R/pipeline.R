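# End-to-end orchestration on synthetic data: simulate, proof, classify,
# engineer covariates, fit and tune, project, evaluate, and compare to the
# generating truth. Every stage records its input/output counts in a
# manifest; the run is a pure function of the configuration.

#' Run the full winter-distribution pipeline on synthetic data
#'
#' Executes, in order: track simulation; location proofing (Argos class,
#' spike, velocity, hourly standardization); season/daytime selection;
#' life-history classification with territory-location removal;
#' behavioural-state filtering; two-per-day thinning; the train/test
#' split; multi-scale covariate selection (mean-ratio screen + VIF);
#' background sampling; optional regularization tuning;
#' contribution-pruned maxent fitting; projection; calibration evaluation;
#' and comparison of the fitted surface against the generating truth.
#'
#' @param config a [simConfig()].
#' @param params [filterParams()].
#' @param extents_m focal-extent ladder for covariate candidates.
#' @param statistics focal statistics for candidates.
#' @param classes maxent feature classes.
#' @param n_knots threshold/hinge knots.
#' @param n_background background points.
#' @param n_random random points for the mean-ratio screen.
#' @param reg_multiplier regularization multiplier, or `NULL` to tune.
#' @param reg_candidates candidates when tuning.
#' @param tune_k holdout iterations when tuning.
#' @param seed seed for the stochastic analysis steps (thinning, split,
#'   background); the generator uses `config$seed`.
#' @return list of stage artifacts, including `surface`, `eval_table`,
#'   `truth_spearman`, `contributions` and a `manifest` of stage counts.
#' @export
runPipeline <- function(config = simConfig(),
                        params = filterParams(),
                        extents_m = c(120, 600, 1200),
                        statistics = c("mean", "sd"),
                        classes = c("linear", "quadratic"),
                        n_knots = 5,
                        n_background = 10000,
                        n_random = 10000,
                        reg_multiplier = 1,
                        reg_candidates = c(0.5, 1, 2, 4),
                        tune_k = 3,
                        seed = 1) {
  manifest <- list()
  note <- function(stage, n_in, n_out)
    manifest[[stage]] <<- data.frame(stage = stage, n_in = n_in,
                                     n_out = n_out)
  stack <- generateCovariateStack(config)
  truth <- trueIntensity(stack, config$betas)
  sim <- generateTracks(config, truth)
  fixes <- sim$fixes
  fixes$fix_id <- seq_len(nrow(fixes))

  f1 <- argosClassFilter(fixes); note("argos_class", nrow(fixes), nrow(f1))
  f2 <- spikeFilter(f1); note("spike", nrow(f1), nrow(f2))
  f3 <- velocityFilter(f2, params$vmax); note("velocity", nrow(f2), nrow(f3))
  f4 <- hourlySubsample(f3); note("hourly", nrow(f3), nrow(f4))
  seas <- seasonDaytimeFilter(f4, params)
  note("season_daytime", nrow(f4),
       nrow(seas$winter) + nrow(seas$summer))

  cls <- classifyDeployments(seas$winter, seas$summer, sim$deployments,
                             studyAreaPolygon(config), config$proj)
  note("life_history", nrow(seas$winter),
       if (is.null(cls$fixes)) 0 else nrow(cls$fixes))
  f5 <- behavioralStateFilter(cls$fixes, params)
  note("behavioral_state", nrow(cls$fixes), nrow(f5))
  f6 <- thinTwoPerDay(f5, seed = seed + 1, params$thin_min_sep_h)
  note("thinning", nrow(f5), nrow(f6))
  sp <- trainTestSplit(f6, params$train_fraction, seed = seed + 2)
  note("train_test", nrow(f6), nrow(sp$train))

  cand <- buildFocalCandidates(stack, extents_m, statistics)
  sel <- selectBestScale(cand, sp$train, n_random = n_random,
                         seed = seed + 3)
  bg <- sampleBackground(sp$train, stack@layers[[1]],
                         buffer_km = 20, n = n_background,
                         seed = seed + 4)
  vf <- vifFilter(sel$stack, bg$points)
  note("covariate_selection", nLayers(cand), nLayers(vf$stack))

  pres_vals <- extractStackValues(vf$stack, sp$train)
  bg_vals <- extractStackValues(vf$stack, bg$points)
  keep <- complete.cases(pres_vals)
  pres_vals <- pres_vals[keep, , drop = FALSE]
  categorical <- vf$stack@meta$name[vf$stack@meta$categorical]

  if (is.null(reg_multiplier)) {
    fs0 <- buildFeatures(bg_vals, categorical, classes, n_knots)
    tun <- tuneRegularization(pres_vals, bg_vals, fs0,
                              candidates = reg_candidates, k = tune_k,
                              seed = seed + 5)
    reg_multiplier <- tun$best
  } else tun <- NULL

  pr <- pruneByContribution(pres_vals, bg_vals, categorical,
                            classes = classes, n_knots = n_knots,
                            reg_multiplier = reg_multiplier)
  final_stack <- subsetStack(vf$stack, pr$covariates)
  surface <- projectModel(pr$model, final_stack,
                          clip_mask = is.finite(truth@values))
  ev <- evalBinTable(surface, sp$test)
  truth_mm <- new("IntensitySurface",
                  values = truth@values / max(truth@values),
                  xll = truth@xll, yll = truth@yll, res = truth@res,
                  crs = truth@crs, scaling = "minmax", area = "study")
  rho <- surfaceCorrelation(surface, truth_mm)
  list(stack = stack, truth = truth, tracks = sim,
       filtered = f6, train = sp$train, test = sp$test,
       labels = cls$labels,
       selection = sel$report, vif_history = vf$history,
       background = bg, tuning = tun,
       model = pr$model, prune_history = pr$history,
       contributions = percentContribution(pr$model),
       surface = surface, eval_table = ev,
       boyce = attr(ev, "boyce"), calibration_r2 = attr(ev, "r2"),
       truth_spearman = rho,
       top10_overlap = topQuantileOverlap(surface, truth_mm, 0.10),
       manifest = do.call(rbind, manifest))
}
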