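# Multi-scale covariate engineering: circular moving-window focal
# statistics, best scale/statistic selection by mean-ratio screening, and
# iterative VIF redundancy removal within variable categories.

.shiftMatrix <- function(m, di, dj) {
  # shift by di rows, dj cols, NA-padded
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

#' Circular moving-window focal statistic
#'
#' Each cell receives the statistic of the cells whose centers lie strictly
#' within `extent_m` meters of it. At `extent_m` equal to the cell size the
#' window is the cell itself and `mean`, `min` and `max` are the identity.
#' Near edges the window is truncated to the available (non-NA) cells, the
#' behaviour a buffered analysis grid relies on.
#'
#' @param base a [GridRaster-class].
#' @param extent_m window radius (m); must be at least the cell size.
#' @param statistic one of `"mean"`, `"sd"`, `"min"`, `"max"`.
#' @return A [GridRaster-class] of the same geometry.
#' @export
focalSummarize <- function(base, extent_m, statistic = c("mean", "sd",
                                                         "min", "max")) {
  statistic <- match.arg(statistic)
  res <- base@res
  if (extent_m < res)
    stop("focal extent must be at least the cell size", call. = FALSE)
  r_cells <- floor((extent_m - 1e-9) / res)
  offs <- expand.grid(di = -r_cells:r_cells, dj = -r_cells:r_cells)
  offs <- offs[(offs$di^2 + offs$dj^2) * res^2 < extent_m^2, , drop = FALSE]
  m <- base@values
  nr <- nrow(m); nc <- ncol(m)
  if (statistic %in% c("mean", "sd")) {
    s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      sh <- .shiftMatrix(m, offs$di[k], offs$dj[k])
      ok <- !is.na(sh)
      sh[!ok] <- 0
      s <- s + sh; s2 <- s2 + sh^2; cnt <- cnt + ok
    }
    mu <- s / cnt
    out <- if (statistic == "mean") mu else {
      v <- (s2 - cnt * mu^2) / pmax(cnt - 1, 1)
      sqrt(pmax(v, 0))
    }
    out[cnt == 0] <- NA_real_
  } else {
    out <- matrix(if (statistic == "min") Inf else -Inf, nr, nc)
    cnt <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      sh <- .shiftMatrix(m, offs$di[k], offs$dj[k])
      ok <- !is.na(sh)
      sh[!ok] <- if (statistic == "min") Inf else -Inf
      out <- if (statistic == "min") pmin(out, sh) else pmax(out, sh)
      cnt <- cnt + ok
    }
    out[cnt == 0] <- NA_real_
  }
  gridRaster(out, xll = base@xll, yll = base@yll, res = res, crs = base@crs)
}

#' Build the multi-scale candidate covariate library
#'
#' Applies [focalSummarize()] to every continuous base layer of a stack
#' over a ladder of extents and a set of statistics; categorical layers are
#' passed through unchanged.
#'
#' @param stack base-variable [CovariateStack-class].
#' @param extents_m vector of window radii (m).
#' @param statistics focal statistics to compute.
#' @return A [CovariateStack-class] of candidate covariates with metadata
#'   (`base`, `extent_m`, `statistic`).
#' @export
buildFocalCandidates <- function(stack,
                                 extents_m = c(120, 300, 600, 1200, 3200,
                                               6400),
                                 statistics = c("mean", "sd")) {
  layers <- list(); meta <- NULL
  for (i in seq_len(nLayers(stack))) {
    mi <- stack@meta[i, ]
    if (mi$categorical) {
      layers[[mi$name]] <- stack@layers[[i]]
      meta <- rbind(meta, mi)
      next
    }
    for (ext in extents_m) for (st in statistics) {
      if (ext == stack@layers[[i]]@res && st != "mean") next
      nm <- sprintf("%s_%gm_%s", mi$base, ext, st)
      layers[[nm]] <- focalSummarize(stack@layers[[i]], ext, st)
      meta <- rbind(meta, data.frame(
        name = nm, base = mi$base, category = mi$category,
        extent_m = ext, statistic = st, categorical = FALSE))
    }
  }
  covariateStack(layers, meta)
}

#' Select the best scale and statistic per base variable
#'
#' For each candidate covariate the selection ratio is the mean value at
#' training locations over the mean value at a uniform random sample of
#' locations in the modeled area. Candidates with fewer than 20% non-zero
#' values at training locations are screened out. The candidate with the
#' largest ratio wins; near-ties (within `tol` relative) are resolved by
#' preferring mid-ladder extents and more interpretable statistics (mean
#' over sd over min over max).
#'
#' @param candidates a [CovariateStack-class] from [buildFocalCandidates()].
#' @param train_xy data.frame of training locations (`x`, `y`, m).
#' @param n_random random locations for the availability mean.
#' @param seed integer seed.
#' @param tol relative near-tie tolerance.
#' @return list with `stack` (one layer per base variable) and `report`
#'   (per-candidate ratios and the selection flag).
#' @export
selectBestScale <- function(candidates, train_xy, n_random = 10000,
                            seed = 1, tol = 0.05) {
  g <- candidates@layers[[1]]
  ext <- rasterExtent(g)
  rnd <- withSeed(seed, data.frame(
    x = runif(n_random, ext["xmin"], ext["xmax"]),
    y = runif(n_random, ext["ymin"], ext["ymax"])))
  meta <- candidates@meta
  report <- NULL
  chosen <- character(0)
  stat_pref <- c(mean = 1, sd = 2, min = 3, max = 4, none = 0)
  for (bv in unique(meta$base)) {
    rows <- which(meta$base == bv)
    if (length(rows) == 1 || meta$categorical[rows[1]]) {
      chosen <- c(chosen, meta$name[rows[1]])
      report <- rbind(report, data.frame(
        name = meta$name[rows[1]], base = bv, ratio = NA_real_,
        nonzero_frac = NA_real_, selected = TRUE))
      next
    }
    cand <- data.frame(name = meta$name[rows], ratio = NA_real_,
                       nonzero_frac = NA_real_)
    for (j in seq_along(rows)) {
      ly <- candidates@layers[[rows[j]]]
      vt <- extractValues(ly, train_xy$x, train_xy$y)
      vr <- extractValues(ly, rnd$x, rnd$y)
      vt <- vt[is.finite(vt)]; vr <- vr[is.finite(vr)]
      cand$nonzero_frac[j] <- mean(vt != 0)
      mr <- mean(vr)
      if (!is.finite(mr) || mr == 0) {
        warning("zero/invalid availability mean for candidate ",
                meta$name[rows[j]], "; skipped")
        next
      }
      cand$ratio[j] <- mean(vt) / mr
    }
    ok <- which(is.finite(cand$ratio) & cand$nonzero_frac >= 0.2)
    if (!length(ok)) {
      warning("no candidate passed screening for base variable ", bv)
      next
    }
    best <- max(cand$ratio[ok])
    near <- ok[cand$ratio[ok] >= best * (1 - tol)]
    if (length(near) > 1) {
      ext_j <- meta$extent_m[rows[near]]
      mid <- stats::median(meta$extent_m[rows])
      pref <- order(stat_pref[meta$statistic[rows[near]]],
                    abs(log(ext_j / mid)))
      sel <- near[pref[1]]
    } else sel <- near
    chosen <- c(chosen, cand$name[sel])
    cand$selected <- seq_len(nrow(cand)) %in% sel
    cand$base <- bv
    report <- rbind(report, cand[, c("name", "base", "ratio",
                                     "nonzero_frac", "selected")])
  }
  list(stack = subsetStack(candidates, chosen), report = report)
}

#' Variance inflation factors of a value matrix
#'
#' Classical VIF: for each column, 1 / (1 - R^2) of its regression on the
#' other columns.
#' @param X numeric matrix (observations x variables).
#' @export
vifValues <- function(X) {
  p <- ncol(X)
  if (p < 2) return(setNames(rep(1, p), colnames(X)))
  vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((X[, j] - mean(X[, j]))^2), 1e-300)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}

#' Remove redundant covariates by iterative VIF filtering
#'
#' Within each variable category, repeatedly removes the covariate with the
#' largest VIF (computed at the supplied sample points) while any VIF is at
#' or above the threshold.
#'
#' @param stack a [CovariateStack-class].
#' @param sample_xy data.frame of sample locations (`x`, `y`), typically
#'   background points.
#' @param threshold VIF removal threshold (default 4).
#' @param group_by_category compute VIFs within categories (default) or
#'   globally.
#' @return list with `stack` (survivors) and `history` (removal order with
#'   the VIF that triggered each removal).
#' @export
vifFilter <- function(stack, sample_xy, threshold = 4,
                      group_by_category = TRUE) {
  meta <- stack@meta
  vals <- vapply(stack@layers,
                 function(l) extractValues(l, sample_xy$x, sample_xy$y),
                 numeric(nrow(sample_xy)))
  ok_rows <- complete.cases(vals)
  vals <- vals[ok_rows, , drop = FALSE]
  groups <- if (group_by_category) split(meta$name, meta$category) else
    list(all = meta$name)
  history <- NULL
  keep <- meta$name
  for (gn in names(groups)) {
    members <- intersect(groups[[gn]], keep)
    cat_flag <- meta$categorical[match(members, meta$name)]
    members_c <- members[!cat_flag]   # categorical layers exempt
    while (length(members_c) >= 2) {
      v <- vifValues(vals[, members_c, drop = FALSE])
      if (any(!is.finite(v))) {
        worst <- names(v)[which(!is.finite(v))[1]]
        warning("perfectly collinear covariate removed: ", worst)
      } else if (max(v) >= threshold) {
        worst <- names(v)[which.max(v)]
      } else break
      history <- rbind(history, data.frame(
        category = gn, removed = worst, vif = unname(v[worst])))
      members_c <- setdiff(members_c, worst)
      keep <- setdiff(keep, worst)
    }
  }
  list(stack = subsetStack(stack, keep), history = history)
}
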