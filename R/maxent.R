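# Penalized maximum-entropy intensity model (inhomogeneous Poisson
# point-process equivalent): feature construction with MaxEnt-style
# class-specific L1 penalties, coordinate-wise proximal optimization of the
# convex penalized log-likelihood, percent-contribution accounting,
# regularization tuning by repeated holdout, contribution pruning, and
# surface projection.

#' Extract stack values at points
#'
#' @param stack a [CovariateStack-class].
#' @param xy data.frame with `x`, `y` (m).
#' @return data.frame, one column per layer.
#' @export
extractStackValues <- function(stack, xy) {
  out <- lapply(stack@layers, extractValues, px = xy$x, py = xy$y)
  as.data.frame(out, check.names = FALSE)
}

# MaxEnt-convention class beta schedules, interpolated on presence sample
# size and clamped at the ends.
.classBeta <- function(type, n) {
  sched <- switch(type,
    linear = , quadratic = , product =
      list(ss = c(0, 10, 17, 30, 100), b = c(1, 1, 0.2, 0.2, 0.05)),
    categorical = list(ss = c(0, 10, 17), b = c(0.65, 0.5, 0.25)),
    threshold = list(ss = c(0, 100), b = c(2, 1)),
    hinge = list(ss = c(0), b = c(0.5)))
  if (length(sched$ss) == 1) return(sched$b)
  approx(sched$ss, sched$b, xout = min(max(n, min(sched$ss)),
                                       max(sched$ss)),
         rule = 2)$y
}

#' Build a feature set from background covariate values
#'
#' Expands covariates into linear, quadratic, pairwise-product, threshold
#' indicator and hinge-ramp features (knots at background quantiles), and
#' class indicators for categorical covariates. Scaling constants mapping
#' every feature to [0, 1] on the background sample are stored; features
#' constant on the background are dropped and logged.
#'
#' @param bg_vals data.frame of covariate values at background points.
#' @param categorical character vector of categorical covariate names.
#' @param classes feature classes to build.
#' @param n_knots number of threshold/hinge knots per covariate.
#' @return A feature-set list (`defs`, scaling constants, covariate names).
#' @export
buildFeatures <- function(bg_vals,
                          categorical = character(0),
                          classes = c("linear", "quadratic", "product",
                                      "threshold", "hinge"),
                          n_knots = 50) {
  covs <- names(bg_vals)
  cont <- setdiff(covs, categorical)
  defs <- NULL
  add <- function(name, type, cov1, cov2 = NA, knot = NA, level = NA) {
    rbind(defs, data.frame(name = name, type = type, cov1 = cov1,
                           cov2 = cov2, knot = knot, level = level,
                           stringsAsFactors = FALSE))
  }
  for (v in cont) {
    if ("linear" %in% classes) defs <- add(v, "linear", v)
    if ("quadratic" %in% classes) defs <- add(paste0(v, "^2"),
                                              "quadratic", v)
  }
  if ("product" %in% classes && length(cont) >= 2) {
    pr <- utils::combn(cont, 2)
    for (k in seq_len(ncol(pr)))
      defs <- add(paste0(pr[1, k], "*", pr[2, k]), "product",
                  pr[1, k], pr[2, k])
  }
  kn_probs <- seq_len(n_knots) / (n_knots + 1)
  for (v in cont) {
    q <- unique(quantile(bg_vals[[v]], probs = kn_probs, names = FALSE,
                         na.rm = TRUE))
    if ("threshold" %in% classes)
      for (t in q) defs <- add(sprintf("I(%s>%.6g)", v, t), "threshold",
                               v, knot = t)
    if ("hinge" %in% classes) {
      xmax <- max(bg_vals[[v]], na.rm = TRUE)
      for (t in q[q < xmax])
        defs <- add(sprintf("h(%s,%.6g)", v, t), "hinge", v, knot = t)
    }
  }
  for (v in categorical) {
    for (lv in sort(unique(bg_vals[[v]])))
      defs <- add(sprintf("%s==%g", v, lv), "categorical", v, level = lv)
  }
  fs <- list(defs = defs, covariates = covs, categorical = categorical,
             train_range = vapply(bg_vals, range, numeric(2),
                                  na.rm = TRUE))
  raw <- .rawFeatureMatrix(fs, bg_vals)
  rng <- apply(raw, 2, range)
  keep <- rng[2, ] - rng[1, ] > 1e-12
  if (any(!keep))
    message("dropping ", sum(!keep), " constant feature(s): ",
            paste(head(colnames(raw)[!keep], 5), collapse = ", "))
  fs$defs <- fs$defs[keep, , drop = FALSE]
  fs$scale_min <- rng[1, keep]
  fs$scale_max <- rng[2, keep]
  fs
}

.rawFeatureMatrix <- function(fs, vals) {
  d <- fs$defs
  out <- matrix(NA_real_, nrow(vals), nrow(d),
                dimnames = list(NULL, d$name))
  for (k in seq_len(nrow(d))) {
    x <- vals[[d$cov1[k]]]
    out[, k] <- switch(d$type[k],
      linear = x,
      quadratic = x^2,
      product = x * vals[[d$cov2[k]]],
      threshold = as.numeric(x > d$knot[k]),
      hinge = {
        xmax <- fs$train_range[2, d$cov1[k]]
        pmax(0, pmin(1, (x - d$knot[k]) / (xmax - d$knot[k])))
      },
      categorical = as.numeric(x == d$level[k]))
  }
  out
}

#' Feature matrix at covariate values
#'
#' Raw features affinely scaled to the [0, 1] background scaling of the
#' feature set. Covariates are clamped to the background (training) range
#' first; the number of clamped values is reported via the
#' `clamped` attribute.
#'
#' @param fs a feature set from [buildFeatures()].
#' @param vals data.frame of covariate values.
#' @param clamp clamp covariates to the training range?
#' @export
featureMatrix <- function(fs, vals, clamp = TRUE) {
  n_clamped <- 0L
  if (clamp) {
    for (v in setdiff(fs$covariates, fs$categorical)) {
      r <- fs$train_range[, v]
      cl <- vals[[v]] < r[1] | vals[[v]] > r[2]
      n_clamped <- n_clamped + sum(cl, na.rm = TRUE)
      vals[[v]] <- pmin(pmax(vals[[v]], r[1]), r[2])
    }
  }
  raw <- .rawFeatureMatrix(fs, vals)
  sc <- sweep(sweep(raw, 2, fs$scale_min), 2,
              fs$scale_max - fs$scale_min, "/")
  attr(sc, "clamped") <- n_clamped
  sc
}

.logMeanExp <- function(eta) {
  m <- max(eta)
  m + log(mean(exp(eta - m)))
}

#' Fit the penalized maximum-entropy model
#'
#' Maximizes the L1-penalized maxent log-likelihood
#' `mean_presence(f . lambda) - log mean_background(exp(f . lambda))
#'  - sum_j beta_j |lambda_j|`
#' by cyclic coordinate-wise proximal updates (soft thresholding with the
#' global curvature bound 1/4 valid for features in [0, 1]); the penalized
#' objective is non-decreasing across updates. Per-feature penalties are
#' `reg_multiplier x class beta(sample size) x sd(feature on background)
#' / sqrt(n_presence)`, the published MaxEnt convention. The relative
#' intensity at covariates `x` is proportional to `exp(f(x) . lambda)`.
#'
#' @param pres_vals,bg_vals data.frames of covariate values at presence and
#'   background points.
#' @param fs feature set from [buildFeatures()].
#' @param reg_multiplier global regularization multiplier.
#' @param max_iter maximum coordinate sweeps.
#' @param tol relative penalized-objective convergence tolerance.
#' @return A [MaxentModel-class].
#' @export
maxentFit <- function(pres_vals, bg_vals, fs, reg_multiplier = 1,
                      max_iter = 2000, tol = 1e-6) {
  Fp <- featureMatrix(fs, pres_vals, clamp = TRUE)
  Fb <- featureMatrix(fs, bg_vals, clamp = FALSE)
  ok_p <- complete.cases(Fp); ok_b <- complete.cases(Fb)
  Fp <- Fp[ok_p, , drop = FALSE]; Fb <- Fb[ok_b, , drop = FALSE]
  np <- nrow(Fp); nb <- nrow(Fb); p <- ncol(Fp)
  beta_j <- vapply(seq_len(p), function(j) {
    reg_multiplier * .classBeta(fs$defs$type[j], np) *
      sd(Fb[, j]) / sqrt(np)
  }, numeric(1))
  names(beta_j) <- colnames(Fp)
  fbar <- colMeans(Fp)
  lambda <- setNames(numeric(p), colnames(Fp))
  eta <- as.vector(Fb %*% lambda)
  Lc <- 0.25  # curvature bound: Var of a [0,1] feature never exceeds 1/4
  obj <- function() sum(fbar * lambda) - .logMeanExp(eta) -
    sum(beta_j * abs(lambda))
  objective <- obj()
  gain <- setNames(numeric(p), colnames(Fp))
  trace <- objective
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- objective
    for (j in seq_len(p)) {
      m <- max(eta)
      w <- exp(eta - m); w <- w / sum(w)
      g <- fbar[j] - sum(w * Fb[, j])
      z <- lambda[j] + g / Lc
      newl <- sign(z) * max(0, abs(z) - beta_j[j] / Lc)
      if (newl != lambda[j]) {
        eta <- eta + Fb[, j] * (newl - lambda[j])
        lambda[j] <- newl
        newobj <- obj()
        gain[j] <- gain[j] + max(newobj - objective, 0)
        objective <- newobj
      }
    }
    trace <- c(trace, objective)
    if (abs(objective - prev) <= tol * (abs(prev) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("maxent optimizer did not reach tolerance ", tol, " in ",
            max_iter, " sweeps; returning current coefficients")
  new("MaxentModel", features = fs, lambda = lambda,
      reg_multiplier = reg_multiplier, beta_j = beta_j,
      gain_credit = gain, objective = trace, converged = converged,
      train_range = fs$train_range, n_presence = np, n_background = nb)
}

#' Penalized maxent objective (for diagnostics and cross-checks)
#'
#' @param lambda coefficient vector.
#' @param Fp,Fb scaled feature matrices (presence, background).
#' @param beta_j per-feature penalties.
#' @export
maxentObjective <- function(lambda, Fp, Fb, beta_j) {
  mean(Fp %*% lambda) - .logMeanExp(as.vector(Fb %*% lambda)) -
    sum(beta_j * abs(lambda))
}

#' Per-covariate percent contribution
#'
#' Positive per-update increases of the penalized objective are credited to
#' the feature updated, aggregated to parent covariates (product features
#' split equally between their two parents) and normalized to 100%.
#'
#' @param model a [MaxentModel-class].
#' @return named numeric vector summing to 100 (or all zero for a null
#'   model).
#' @export
percentContribution <- function(model) {
  fs <- model@features
  contrib <- setNames(numeric(length(fs$covariates)), fs$covariates)
  for (k in seq_len(nrow(fs$defs))) {
    g <- model@gain_credit[k]
    if (fs$defs$type[k] == "product") {
      contrib[fs$defs$cov1[k]] <- contrib[fs$defs$cov1[k]] + g / 2
      contrib[fs$defs$cov2[k]] <- contrib[fs$defs$cov2[k]] + g / 2
    } else {
      contrib[fs$defs$cov1[k]] <- contrib[fs$defs$cov1[k]] + g
    }
  }
  tot <- sum(contrib)
  if (tot <= 0) return(contrib)
  100 * contrib / tot
}

#' Sample background points from the modeled area
#'
#' The modeled area is the union of `buffer_km` discs around the training
#' locations, rasterized on the analysis grid (optionally intersected with
#' a study-area mask); points are drawn uniformly by sampling mask cells
#' and jittering within cells.
#'
#' @param train_xy data.frame of training locations (`x`, `y`, m).
#' @param grid a [GridRaster-class] defining the analysis grid.
#' @param buffer_km buffer radius (km).
#' @param n number of background points.
#' @param seed integer seed.
#' @param clip_mask optional logical matrix (same geometry) to intersect.
#' @return list with `points` (data.frame), `mask` (0/1 [GridRaster-class])
#'   and `area_km2`.
#' @export
sampleBackground <- function(train_xy, grid, buffer_km = 20, n = 100000,
                             seed = 1, clip_mask = NULL) {
  if (nrow(train_xy) < 1) stop("at least one training location required",
                               call. = FALSE)
  v <- grid@values
  pres <- matrix(0, nrow(v), ncol(v))
  idx <- cellIndex(grid, train_xy$x, train_xy$y)
  ok <- !is.na(idx$row)
  pres[cbind(idx$row[ok], idx$col[ok])] <- 1
  mask <- .dilateMask(pres, buffer_km * 1000 / grid@res)
  if (!is.null(clip_mask)) mask <- mask & clip_mask
  if (!any(mask))
    stop("modeled area is empty after intersection", call. = FALSE)
  mask_r <- gridRaster(mask + 0, xll = grid@xll, yll = grid@yll,
                       res = grid@res, crs = grid@crs)
  cc <- cellCenters(mask_r)
  cells <- which(cc$value > 0)
  pts <- withSeed(seed, {
    pick <- cells[sample.int(length(cells), n, replace = TRUE)]
    r <- grid@res
    data.frame(x = cc$x[pick] + runif(n, -r / 2, r / 2),
               y = cc$y[pick] + runif(n, -r / 2, r / 2))
  })
  list(points = pts, mask = mask_r,
       area_km2 = length(cells) * cellArea(grid))
}

# binary dilation by a disc of the given radius (cells), zero-padded FFT
.dilateMask <- function(m, radius_cells) {
  nr <- nrow(m); nc <- ncol(m)
  pr <- ceiling(radius_cells) + 1
  NR <- nr + 2 * pr; NC <- nc + 2 * pr
  big <- matrix(0, NR, NC)
  big[pr + seq_len(nr), pr + seq_len(nc)] <- m
  wr <- pmin(0:(NR - 1), NR - 0:(NR - 1))
  wc <- pmin(0:(NC - 1), NC - 0:(NC - 1))
  disc <- outer(wr^2, wc^2, "+") <= radius_cells^2
  conv <- Re(stats::fft(stats::fft(big) * stats::fft(disc + 0),
                        inverse = TRUE)) / (NR * NC)
  (conv > 0.5)[pr + seq_len(nr), pr + seq_len(nc)]
}

#' Tune the regularization multiplier by repeated holdout
#'
#' For each candidate multiplier, `k` random holdouts of about
#' `holdout_frac` of the presence data are scored: the model is refitted on
#' the remainder and the binned calibration R-squared of the holdout
#' against the refitted predictions (background sample as the area
#' measure) is recorded. The candidate with the largest mean R-squared
#' wins; ties go to the larger (more general) multiplier.
#'
#' @param pres_vals,bg_vals covariate values at presence/background points.
#' @param fs feature set.
#' @param candidates candidate multipliers.
#' @param k holdout iterations per candidate.
#' @param holdout_frac holdout fraction.
#' @param seed integer seed.
#' @param n_bins calibration bins.
#' @param ... passed to [maxentFit()].
#' @return list with `best` (multiplier) and `cv` (per-candidate,
#'   per-iteration R-squared table).
#' @export
tuneRegularization <- function(pres_vals, bg_vals, fs,
                               candidates = c(0.5, 1, 2, 4, 8),
                               k = 10, holdout_frac = 0.25, seed = 1,
                               n_bins = 10, ...) {
  stopifnot(length(candidates) >= 1)
  np <- nrow(pres_vals)
  splits <- withSeed(seed, lapply(seq_len(k), function(i)
    sample.int(np, max(1, round(np * holdout_frac)))))
  cv <- NULL
  for (m in candidates) {
    for (i in seq_len(k)) {
      ho <- splits[[i]]
      fit <- maxentFit(pres_vals[-ho, , drop = FALSE], bg_vals, fs,
                       reg_multiplier = m, ...)
      pr_ho <- predictIntensity(fit, pres_vals[ho, , drop = FALSE])
      pr_bg <- predictIntensity(fit, bg_vals)
      tab <- evalBinTableFromValues(pr_ho / max(pr_bg),
                                    pr_bg / max(pr_bg), n_bins = n_bins)
      cv <- rbind(cv, data.frame(multiplier = m, iter = i,
                                 r2 = calibrationR2(tab$observed,
                                                    tab$predicted)))
    }
  }
  means <- aggregate(r2 ~ multiplier, cv, mean)
  best <- max(means$multiplier[means$r2 >= max(means$r2) - 1e-12])
  list(best = best, cv = cv, means = means)
}

#' Predict relative intensity at covariate values
#'
#' `exp(f(x) . lambda)`, unscaled.
#' @param model a [MaxentModel-class].
#' @param vals data.frame of covariate values.
#' @export
predictIntensity <- function(model, vals) {
  Fm <- featureMatrix(model@features, vals, clamp = TRUE)
  as.vector(exp(Fm %*% model@lambda))
}

#' Prune covariates by percent contribution
#'
#' Iteratively refits and removes all covariates contributing less than
#' `min_pct` percent until none do or `max_rounds` is reached.
#'
#' @param pres_vals,bg_vals covariate values.
#' @param categorical categorical covariate names.
#' @param min_pct contribution threshold (percent).
#' @param max_rounds maximum refit rounds.
#' @param classes,n_knots feature construction options.
#' @param ... passed to [maxentFit()].
#' @return list with `model` (final fit), `covariates` (surviving set) and
#'   `history` of removals.
#' @export
pruneByContribution <- function(pres_vals, bg_vals,
                                categorical = character(0),
                                min_pct = 1, max_rounds = 3,
                                classes = c("linear", "quadratic"),
                                n_knots = 5, reg_multiplier = 1, ...) {
  covs <- names(bg_vals)
  history <- NULL
  model <- NULL
  for (round in seq_len(max_rounds)) {
    fs <- buildFeatures(bg_vals[covs], intersect(categorical, covs),
                        classes = classes, n_knots = n_knots)
    model <- maxentFit(pres_vals[covs], bg_vals[covs], fs,
                       reg_multiplier = reg_multiplier, ...)
    pc <- percentContribution(model)
    low <- names(pc)[pc < min_pct]
    if (!length(low)) break
    if (length(low) >= length(covs))
      stop("all covariates pruned: degenerate model", call. = FALSE)
    history <- rbind(history, data.frame(round = round, removed = low,
                                         pct = unname(pc[low])))
    covs <- setdiff(covs, low)
  }
  list(model = model, covariates = covs, history = history)
}

#' Project a fitted model to a raster stack
#'
#' Computes `exp(f(x) . lambda)` per cell over the projection area,
#' min-max scales to [0, 1] over the cells of the clip mask, then clips.
#' Covariates outside the training range are clamped (count reported via
#' attribute `clamped`).
#'
#' @param model a [MaxentModel-class].
#' @param stack a [CovariateStack-class] covering the projection area.
#' @param clip_mask optional logical matrix: cells defining the final
#'   (study) area; scaling constants are computed over these cells.
#' @return An [IntensitySurface-class] with `scaling = "minmax"`.
#' @export
projectModel <- function(model, stack, clip_mask = NULL) {
  g <- stack@layers[[1]]
  cc <- cellCenters(g)
  vals <- as.data.frame(lapply(stack@layers, function(l) as.vector(l@values)),
                        check.names = FALSE)
  vals <- vals[model@features$covariates]
  Fm <- featureMatrix(model@features, vals, clamp = TRUE)
  eta <- as.vector(Fm %*% model@lambda)
  raw <- matrix(NA_real_, nrow(g@values), ncol(g@values))
  raw[cbind(cc$row, cc$col)] <- exp(eta)
  if (is.null(clip_mask)) clip_mask <- !is.na(raw)
  inside <- raw[clip_mask]
  lo <- min(inside, na.rm = TRUE); hi <- max(inside, na.rm = TRUE)
  scaled <- (raw - lo) / max(hi - lo, 1e-300)
  scaled <- pmin(pmax(scaled, 0), 1)
  scaled[!clip_mask] <- NA_real_
  out <- new("IntensitySurface", values = scaled, xll = g@xll, yll = g@yll,
             res = g@res, crs = g@crs, scaling = "minmax", area = "study")
  attr(out, "clamped") <- attr(Fm, "clamped")
  out
}
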