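# Calibration evaluation suite: equal-interval intensity bins, observed
# and predicted location counts, calibration R-squared, area-adjusted
# frequencies (AAF), the (squared) Boyce index, AAF magnitude-of-difference,
# repeated-holdout cross-validation summaries, per-region calibration, and
# grid quartile concordance.

#' Equal-interval intensity bins of a surface
#'
#' Bin `b` covers `((b-1)/n, b/n]` of the [0, 1] intensity scale; bin 1
#' includes 0. NA cells are outside every bin.
#'
#' @param surface an [IntensitySurface-class] (min-max scaled).
#' @param n_bins number of bins (default 10).
#' @return list with `bins` (integer [GridRaster-class]) and `area_km2`
#'   (per-bin area).
#' @export
binSurface <- function(surface, n_bins = 10) {
  v <- surface@values
  b <- ceiling(v * n_bins)
  b[v <= 0] <- 1
  b[b > n_bins] <- n_bins
  areas <- vapply(seq_len(n_bins),
                  function(k) sum(b == k, na.rm = TRUE) * cellArea(surface),
                  numeric(1))
  list(bins = gridRaster(b, xll = surface@xll, yll = surface@yll,
                         res = surface@res, crs = surface@crs),
       area_km2 = areas)
}

#' Per-bin predicted location counts
#'
#' `predicted_b = n_test x (sum of intensity over bin-b cells) / (total
#' intensity)`.
#'
#' @param surface an [IntensitySurface-class].
#' @param bins the `bins` raster from [binSurface()].
#' @param n_test number of evaluation locations.
#' @param n_bins number of bins.
#' @export
predictedCounts <- function(surface, bins, n_test, n_bins = 10) {
  assertAligned(surface, bins)
  v <- surface@values; b <- bins@values
  tot <- sum(v, na.rm = TRUE)
  vapply(seq_len(n_bins), function(k)
    n_test * sum(v[b == k & !is.na(b)], na.rm = TRUE) / tot, numeric(1))
}

#' Per-bin observed location counts
#'
#' @param bins the `bins` raster from [binSurface()].
#' @param test_xy data.frame of evaluation locations (`x`, `y`).
#' @param n_bins number of bins.
#' @export
observedCounts <- function(bins, test_xy, n_bins = 10) {
  bb <- extractValues(bins, test_xy$x, test_xy$y)
  vapply(seq_len(n_bins), function(k) sum(bb == k, na.rm = TRUE),
         numeric(1))
}

#' Calibration R-squared
#'
#' Squared Pearson correlation between observed and predicted per-bin
#' counts.
#' @param observed,predicted per-bin counts.
#' @export
calibrationR2 <- function(observed, predicted) {
  if (sd(observed) == 0 || sd(predicted) == 0) return(NA_real_)
  cor(observed, predicted)^2
}

#' Area-adjusted frequencies
#'
#' `AAF_b = (observed_b / total observed) / (area_b / total area)`; bins
#' with zero area get `NA` (excluded downstream).
#'
#' @param observed per-bin observed counts.
#' @param area_km2 per-bin areas.
#' @export
aaf <- function(observed, area_km2) {
  rel_obs <- observed / sum(observed)
  rel_area <- area_km2 / sum(area_km2)
  out <- rel_obs / rel_area
  out[rel_area == 0] <- NA_real_
  out
}

#' Boyce index (squared rank correlation of AAF with bin rank)
#'
#' Spearman rank correlation (mid-rank ties) between the AAF values and
#' their bin indices, squared for reporting; the raw correlation is
#' attached as attribute `rho`. Bins with undefined AAF are excluded.
#'
#' @param aaf_values per-bin AAF.
#' @param ranks bin ranks (default `seq_along`).
#' @export
boyceIndex <- function(aaf_values, ranks = seq_along(aaf_values)) {
  ok <- is.finite(aaf_values)
  rho <- cor(aaf_values[ok], ranks[ok], method = "spearman")
  out <- rho^2
  attr(out, "rho") <- rho
  out
}

#' AAF magnitude of difference
#'
#' AAF of the highest bin divided by the AAF of the lowest-index bin with
#' positive AAF (when the lowest bin holds no locations the next occupied
#' bin is the denominator), rounded to integer.
#'
#' @param aaf_values per-bin AAF in bin order.
#' @param rounded round to integer (default TRUE)?
#' @export
aafMagnitude <- function(aaf_values, rounded = TRUE) {
  ok <- which(is.finite(aaf_values))
  hi <- aaf_values[max(ok)]
  pos <- ok[aaf_values[ok] > 0]
  if (!length(pos)) return(NA_real_)
  ratio <- hi / aaf_values[min(pos)]
  if (rounded) round(ratio) else ratio
}

#' Full evaluation bin table for a surface and test locations
#'
#' @param surface min-max scaled [IntensitySurface-class].
#' @param test_xy evaluation locations (`x`, `y`).
#' @param n_bins number of bins.
#' @return data.frame (bin, area_km2, area_prop, observed, predicted, aaf)
#'   with scalar attributes `r2`, `boyce`, `boyce_rho`, `magnitude`.
#' @export
evalBinTable <- function(surface, test_xy, n_bins = 10) {
  bs <- binSurface(surface, n_bins)
  obs <- observedCounts(bs$bins, test_xy, n_bins)
  pred <- predictedCounts(surface, bs$bins, sum(obs), n_bins)
  a <- aaf(obs, bs$area_km2)
  tab <- data.frame(bin = seq_len(n_bins), area_km2 = bs$area_km2,
                    area_prop = bs$area_km2 / sum(bs$area_km2),
                    observed = obs, predicted = pred, aaf = a)
  attr(tab, "r2") <- calibrationR2(obs, pred)
  b <- boyceIndex(a)
  attr(tab, "boyce") <- as.numeric(b)
  attr(tab, "boyce_rho") <- attr(b, "rho")
  attr(tab, "magnitude") <- aafMagnitude(a)
  tab
}

#' Evaluation bin table from point-level predictions
#'
#' Monte-Carlo version of [evalBinTable()] for use without a projected
#' raster: scaled intensities at evaluation locations and at an area
#' sample (background points) stand in for the surface; the background
#' sample's bin shares measure area.
#'
#' @param test_vals scaled intensity at evaluation locations ([0, 1]).
#' @param area_vals scaled intensity at the area sample.
#' @param n_bins number of bins.
#' @export
evalBinTableFromValues <- function(test_vals, area_vals, n_bins = 10) {
  bin_of <- function(v) pmin(pmax(ceiling(v * n_bins), 1), n_bins)
  tb <- bin_of(test_vals); ab <- bin_of(area_vals)
  obs <- vapply(seq_len(n_bins), function(k) sum(tb == k), numeric(1))
  area <- vapply(seq_len(n_bins), function(k) sum(ab == k), numeric(1))
  tot <- sum(area_vals)
  pred <- vapply(seq_len(n_bins), function(k)
    length(test_vals) * sum(area_vals[ab == k]) / tot, numeric(1))
  data.frame(bin = seq_len(n_bins), area_km2 = area,
             area_prop = area / sum(area), observed = obs,
             predicted = pred, aaf = aaf(obs, area))
}

#' Repeated-holdout cross-validation of the calibration evaluation
#'
#' `k` random holdouts of about `holdout_frac` of the training presences;
#' the model is refitted on the remainder and per-bin observed and
#' predicted counts recorded; per-bin means and normal-theory 95%
#' confidence intervals across iterations are returned.
#'
#' @param pres_vals,bg_vals covariate values at presence/background points.
#' @param fs feature set from [buildFeatures()].
#' @param k iterations.
#' @param holdout_frac holdout fraction (default 0.22).
#' @param seed integer seed.
#' @param n_bins bins.
#' @param reg_multiplier regularization multiplier for the refits.
#' @param ... passed to [maxentFit()].
#' @return list with `summary` (per-bin means and CIs) and `iterations`.
#' @export
crossValidate <- function(pres_vals, bg_vals, fs, k = 10,
                          holdout_frac = 0.22, seed = 1, n_bins = 10,
                          reg_multiplier = 1, ...) {
  np <- nrow(pres_vals)
  splits <- withSeed(seed, lapply(seq_len(k), function(i)
    sample.int(np, max(1, round(np * holdout_frac)))))
  rows <- NULL
  for (i in seq_len(k)) {
    ho <- splits[[i]]
    fit <- maxentFit(pres_vals[-ho, , drop = FALSE], bg_vals, fs,
                     reg_multiplier = reg_multiplier, ...)
    pr_bg <- predictIntensity(fit, bg_vals)
    pr_ho <- predictIntensity(fit, pres_vals[ho, , drop = FALSE])
    mx <- max(pr_bg)
    tab <- evalBinTableFromValues(pr_ho / mx, pr_bg / mx, n_bins)
    rows <- rbind(rows, data.frame(iter = i, tab))
  }
  ci <- function(v) {
    m <- mean(v); s <- sd(v) / sqrt(length(v))
    c(mean = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
  }
  summ <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sub <- rows[rows$bin == b, ]
    data.frame(bin = b, t(ci(sub$observed)),
               pred_mean = mean(sub$predicted),
               pred_lo = ci(sub$predicted)["lo"],
               pred_hi = ci(sub$predicted)["hi"])
  }))
  rownames(summ) <- NULL
  list(summary = summ, iterations = rows)
}

#' Per-region calibration
#'
#' Runs the binned observed/predicted evaluation within each polygon and
#' pools the region-bin pairs into one R-squared.
#'
#' @param surface min-max scaled [IntensitySurface-class].
#' @param test_xy evaluation locations.
#' @param polygons named list of rings (matrices, m).
#' @param n_bins bins.
#' @return list with `regions` (per-region bin tables), `pooled_r2`.
#' @export
subregionCalibration <- function(surface, test_xy, polygons, n_bins = 10) {
  out <- list()
  allobs <- allpred <- NULL
  for (nm in names(polygons)) {
    ring <- polygons[[nm]]
    cc <- cellCenters(surface)
    inside <- pointInPolygon(cc$x, cc$y, ring) & !is.na(cc$value)
    sub <- surface
    vv <- sub@values
    mask <- matrix(FALSE, nrow(vv), ncol(vv))
    mask[cbind(cc$row[inside], cc$col[inside])] <- TRUE
    vv[!mask] <- NA_real_
    sub@values <- vv
    pin <- pointInPolygon(test_xy$x, test_xy$y, ring)
    tab <- evalBinTable(sub, test_xy[pin, , drop = FALSE], n_bins)
    out[[nm]] <- tab
    allobs <- c(allobs, tab$observed)
    allpred <- c(allpred, tab$predicted)
  }
  list(regions = out, pooled_r2 = calibrationR2(allobs, allpred))
}

#' Grid quartile concordance of observed and predicted counts
#'
#' Overlays a coarse square grid on the modeling area. Each raster cell is
#' assigned the AAF of its intensity bin; a coarse cell's predicted count
#' is its mean AAF times its share of the modeling area times the total
#' test count. Predicted and observed counts over cells containing test
#' data are split into quartile bins; discordance is the absolute quartile
#' difference.
#'
#' @param surface min-max scaled [IntensitySurface-class] (NA outside the
#'   modeling area).
#' @param test_xy evaluation locations.
#' @param cell_km coarse cell size (km).
#' @param n_bins intensity bins for the AAF step.
#' @return data.frame per coarse cell: observed, predicted, quartiles,
#'   discordance, and an `excluded` flag for cells without test data.
#' @export
gridConcordance <- function(surface, test_xy, cell_km = 30, n_bins = 10) {
  bs <- binSurface(surface, n_bins)
  obs <- observedCounts(bs$bins, test_xy, n_bins)
  a <- aaf(obs, bs$area_km2)
  cc <- cellCenters(surface)
  valid <- !is.na(cc$value)
  aaf_cell <- a[rasterValues(bs$bins)[cbind(cc$row, cc$col)]]
  ext <- rasterExtent(surface)
  csz <- cell_km * 1000
  gx <- floor((cc$x - ext["xmin"]) / csz)
  gy <- floor((cc$y - ext["ymin"]) / csz)
  gkey <- paste(gx, gy)
  n_total <- sum(valid)
  tx <- floor((test_xy$x - ext["xmin"]) / csz)
  ty <- floor((test_xy$y - ext["ymin"]) / csz)
  tkey <- paste(tx, ty)
  keys <- sort(unique(gkey[valid]))
  pred <- obs_n <- numeric(length(keys))
  for (i in seq_along(keys)) {
    sel <- valid & gkey == keys[i]
    pred[i] <- mean(aaf_cell[sel], na.rm = TRUE) *
      (sum(sel) / n_total) * nrow(test_xy)
    obs_n[i] <- sum(tkey == keys[i])
  }
  df <- data.frame(cell = keys, observed = obs_n, predicted = pred,
                   excluded = obs_n == 0)
  inc <- !df$excluded
  # rank-based quartiles stay well-defined under ties (a constant vector
  # lands every cell in the middle of the ranking)
  qbin <- function(v) {
    q <- as.integer(ceiling(4 * rank(v, ties.method = "average") /
                              length(v)))
    pmin(pmax(q, 1L), 4L)
  }
  df$obs_quartile <- NA_integer_; df$pred_quartile <- NA_integer_
  df$obs_quartile[inc] <- qbin(df$observed[inc])
  df$pred_quartile[inc] <- qbin(df$predicted[inc])
  df$discordance <- abs(df$obs_quartile - df$pred_quartile)
  df
}
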