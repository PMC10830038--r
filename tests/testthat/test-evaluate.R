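# Evaluation suite: bins, counts, AAF, Boyce, magnitudes, CV, regions,
# grid concordance.

mkSurface <- function(v, res = 1000) {
  new("IntensitySurface", values = v, xll = 0, yll = 0, res = res,
      crs = "laea", scaling = "minmax", area = "study")
}

test_that("equal-interval binning covers (0,0.1], ..., (0.9,1] with bin 1 holding 0", {
  s <- mkSurface(matrix(0.55, 10, 10))
  bs <- binSurface(s)
  expect_true(all(rasterValues(bs$bins) == 6))
  expect_equal(bs$area_km2[6], 100 * cellArea(s))
  expect_equal(sum(bs$area_km2), 100 * cellArea(s))
  # linear ramp -> each bin holds ~10% of the area
  ramp <- mkSurface(matrix(seq(0, 1, length.out = 400), 20, 20))
  bs2 <- binSurface(ramp)
  expect_true(all(abs(bs2$area_km2 / sum(bs2$area_km2) - 0.1) <=
                    1 / 400 + 1e-12))
  # zeros fall in bin 1, exact bin edges stay in the lower bin
  s3 <- mkSurface(matrix(c(0, 0.1, 0.100001, 1), 2, 2))
  expect_equal(sort(as.vector(rasterValues(binSurface(s3)$bins))),
               c(1, 1, 2, 10))
})

test_that("predicted counts allocate n_test by intensity mass and conserve it", {
  set.seed(3)
  v <- matrix(runif(400), 20, 20)
  s <- mkSurface(v)
  bs <- binSurface(s)
  pred <- predictedCounts(s, bs$bins, 250)
  expect_equal(sum(pred), 250, tolerance = 1e-9)
  # brute-force per-cell summation oracle
  b <- rasterValues(bs$bins)
  for (k in c(1, 5, 10))
    expect_equal(pred[k], 250 * sum(v[b == k]) / sum(v), tolerance = 1e-12)
  # uniform surface -> counts proportional to bin areas
  su <- mkSurface(matrix(0.35, 10, 10))
  bsu <- binSurface(su)
  predu <- predictedCounts(su, bsu$bins, 100)
  expect_equal(predu[4], 100)
  # all intensity concentrated in bin-10 cells
  v2 <- matrix(0, 10, 10); v2[1, 1] <- 1
  s2 <- mkSurface(v2)
  bs2 <- binSurface(s2)
  expect_equal(predictedCounts(s2, bs2$bins, 77)[10], 77)
})

test_that("calibration R2 is the squared Pearson correlation", {
  obs <- c(2, 5, 9, 14, 22, 30, 41, 55, 70, 90)
  expect_equal(calibrationR2(obs, obs), 1)
  expect_equal(calibrationR2(obs, 3 * obs + 7), 1)
  set.seed(8)
  pred <- obs + rnorm(10, 0, 5)
  num <- sum((obs - mean(obs)) * (pred - mean(pred)))
  den <- sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(calibrationR2(obs, pred), (num / den)^2, tolerance = 1e-12)
})

test_that("AAF is relative frequency over relative area", {
  # observations proportional to area -> all AAF 1
  area <- c(40, 30, 20, 10)
  obs <- area * 3
  expect_equal(aaf(obs, area), rep(1, 4))
  # hand-computed case
  obs2 <- c(10, 0, 30, 60)
  a2 <- aaf(obs2, area)
  expect_equal(a2[1], (10 / 100) / (40 / 100))
  expect_equal(a2[2], 0)
  expect_equal(a2[4], (60 / 100) / (10 / 100))
  # the AAF identity: sum over bins of AAF x area share = 1
  expect_equal(sum(a2 * area / sum(area)), 1, tolerance = 1e-12)
  # zero-area bins are undefined, not zero
  expect_true(is.na(aaf(c(1, 0), c(10, 0))[2]))
})

test_that("squared Boyce index reproduces the published worked examples", {
  tab <- lifeHistoryAAFTable()
  expect_equal(as.numeric(round(boyceIndex(tab$adult_migrant), 3)), 0.976, ignore_attr = TRUE)
  expect_equal(as.numeric(round(boyceIndex(tab$adult_nonmigrant), 3)), 1.000, ignore_attr = TRUE)
  expect_equal(as.numeric(round(boyceIndex(tab$nonadult_migrant), 3)), 1.000, ignore_attr = TRUE)
  expect_equal(as.numeric(round(boyceIndex(tab$nonadult_nonmigrant), 3)), 0.976, ignore_attr = TRUE)
  # any strictly increasing AAF sequence scores exactly 1
  expect_equal(as.numeric(boyceIndex(sort(runif(10)))), 1)
  # raw correlation is retained in [-1, 1]
  expect_lte(abs(attr(boyceIndex(tab$adult_migrant), "rho")), 1)
})

test_that("AAF magnitude uses the highest bin over the lowest occupied bin", {
  tab <- lifeHistoryAAFTable()
  expect_equal(aafMagnitude(tab$nonadult_migrant), 162)
  # lowest bin empty: ratio of bins 10:2
  expect_equal(aafMagnitude(tab$nonadult_nonmigrant), 51)
  expect_equal(aafMagnitude(rep(1, 10)), 1)
})

test_that("cross-validation is seeded and degenerates to one split at k = 1", {
  sim <- smallSim()
  pres <- samplePresence(sim$truth, 300, seed = 2)
  cc <- cellCenters(sim$stack@layers[[1]])
  bg <- data.frame(x = cc$x, y = cc$y)[sample.int(3600, 1200), ]
  cont <- setdiff(names(stackLayers(sim$stack)), "ecoregion")
  pv <- extractStackValues(subsetStack(sim$stack, cont), pres)
  bv <- extractStackValues(subsetStack(sim$stack, cont), bg)
  fs <- buildFeatures(bv, classes = "linear")
  cv1 <- crossValidate(pv, bv, fs, k = 1, seed = 9)
  expect_equal(nrow(cv1$iterations), 10)      # 10 bins x 1 iteration
  cv2 <- crossValidate(pv, bv, fs, k = 3, seed = 9)
  cv3 <- crossValidate(pv, bv, fs, k = 3, seed = 9)
  expect_identical(cv2$summary, cv3$summary)
  expect_true(all(cv2$summary$hi >= cv2$summary$lo))
})

test_that("per-region calibration conserves counts and matches the global run", {
  sim <- smallSim()
  surf <- mkSurface(rasterValues(sim$truth) / max(rasterValues(sim$truth)),
                    res = 120)
  surf@xll <- sim$truth@xll; surf@yll <- sim$truth@yll
  pts <- samplePresence(sim$truth, 400, seed = 7)
  ext <- rasterExtent(surf)
  whole <- rectPolygon(ext + c(-1, 1, -1, 1))
  one <- subregionCalibration(surf, pts, list(all = whole))
  glob <- evalBinTable(surf, pts)
  expect_equal(one$regions$all$observed, glob$observed)
  expect_equal(one$pooled_r2, attr(glob, "r2"))
  # two disjoint halves partition the observations
  mid <- mean(ext[c("xmin", "xmax")])
  west <- rectPolygon(c(ext["xmin"] - 1, mid, ext["ymin"] - 1,
                        ext["ymax"] + 1))
  east <- rectPolygon(c(mid, ext["xmax"] + 1, ext["ymin"] - 1,
                        ext["ymax"] + 1))
  two <- subregionCalibration(surf, pts, list(w = west, e = east))
  expect_equal(two$regions$w$observed + two$regions$e$observed,
               glob$observed)
})

test_that("grid concordance quartiles match an independent quantile oracle", {
  set.seed(5)
  v <- matrix(runif(3600), 60, 60)
  s <- mkSurface(v, res = 1000)
  pts <- data.frame(x = runif(400, 0, 60000), y = runif(400, 0, 60000))
  ge <- gridConcordance(s, pts, cell_km = 15)
  expect_equal(nrow(ge), 16)
  inc <- !ge$excluded
  # independent mid-rank quartile routine (sorted-position averaging
  # rather than rank())
  oracle_q <- function(vv) {
    sv <- sort(vv)
    pos <- vapply(vv, function(z) mean(which(sv == z)), numeric(1))
    pmin(pmax(as.integer(ceiling(4 * pos / length(vv))), 1L), 4L)
  }
  expect_equal(ge$obs_quartile[inc], oracle_q(ge$observed[inc]))
  expect_equal(ge$pred_quartile[inc], oracle_q(ge$predicted[inc]))
  expect_equal(ge$discordance[inc],
               abs(ge$obs_quartile[inc] - ge$pred_quartile[inc]))
  # a cell covering the whole region predicts the full test count
  ge1 <- gridConcordance(s, pts, cell_km = 60)
  expect_equal(ge1$predicted, 400, tolerance = 1e-9)
  # uniform surface + uniform points: most cells concordant within 1
  su <- mkSurface(matrix(0.5, 60, 60), res = 1000)
  geu <- gridConcordance(su, pts, cell_km = 15)
  expect_gte(mean(geu$discordance[!geu$excluded] <= 1), 0.7)
})

test_that("evaluation tables from point predictions mirror the raster route", {
  sim <- smallSim()
  v <- rasterValues(sim$truth) / max(rasterValues(sim$truth))
  surf <- mkSurface(v, res = 120)
  surf@xll <- sim$truth@xll; surf@yll <- sim$truth@yll
  pts <- samplePresence(sim$truth, 500, seed = 3)
  tab_r <- evalBinTable(surf, pts)
  # the Monte-Carlo route with the full cell set as the area sample
  cc <- cellCenters(surf)
  test_vals <- extractValues(surf, pts$x, pts$y)
  tab_v <- evalBinTableFromValues(test_vals, cc$value)
  expect_equal(tab_v$observed, tab_r$observed)
  expect_equal(tab_v$predicted, tab_r$predicted, tolerance = 1e-9)
})
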