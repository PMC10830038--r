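# Proofing, seasonal selection, behavioural state, thinning, splitting.

mkfix <- function(x, y, t, dep = "d1",
                  start = as.POSIXct("2016-01-05 17:00:00", tz = "UTC")) {
  data.frame(deployment_id = dep, timestamp = start + t,
             x = x, y = y, lon = -107.5, lat = 43,
             fix_type = "GPS", argos_class = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("Argos class screening keeps GPS and classes 3/2/1 only", {
  f <- data.frame(deployment_id = "d", timestamp = Sys.time() + 1:8,
                  x = 0, y = 0, lon = 0, lat = 0,
                  fix_type = c(rep("GPS", 2), rep("Argos", 6)),
                  argos_class = c(NA, NA, "3", "2", "1", "0", "A", "B"))
  out <- argosClassFilter(f)
  expect_equal(nrow(out), 5)
  expect_equal(nrow(removedFixes(out)), 3)
  expect_true(all(removedFixes(out)$reason == "argos_class"))
  # empty input passes through
  expect_equal(nrow(argosClassFilter(f[0, ])), 0)
  f$fix_type[1] <- "Doppler"
  expect_error(argosClassFilter(f), "unknown fix source")
})

test_that("spike filter removes out-and-back spikes by the angle/length pairs", {
  # collinear equally spaced track: no spikes
  tr <- mkfix(seq(0, 30000, by = 3000), 0, 3600 * (0:10))
  expect_equal(nrow(spikeFilter(tr)), 11)
  # 3-km out-and-back, 10 degree interior angle -> removed
  ang <- 10 * pi / 180
  spike <- mkfix(c(0, 3000 * cos(ang / 2), 3000 * cos(ang / 2) * 0 + 100),
                 c(0, 3000 * sin(ang / 2), 0), 3600 * (0:2))
  # construct precisely: A=(0,0), B at 3 km, C such that angle at B is 10 deg
  A <- c(0, 0); B <- c(3000, 0)
  C <- B + 3000 * c(cos(pi - ang), sin(pi - ang))
  tr <- mkfix(c(A[1], B[1], C[1]), c(A[2], B[2], C[2]), 3600 * (0:2))
  out <- spikeFilter(tr)
  expect_equal(nrow(out), 2)
  expect_equal(removedFixes(out)$x, 3000)
  # same geometry, 2-km legs: length rule not met -> retained
  B2 <- c(2000, 0); C2 <- B2 + 2000 * c(cos(pi - ang), sin(pi - ang))
  tr2 <- mkfix(c(0, B2[1], C2[1]), c(0, B2[2], C2[2]), 3600 * (0:2))
  expect_equal(nrow(spikeFilter(tr2)), 3)
  # 20 degrees with 6-km legs triggers the second rule only
  ang2 <- 20 * pi / 180
  B3 <- c(6000, 0); C3 <- B3 + 6000 * c(cos(pi - ang2), sin(pi - ang2))
  tr3 <- mkfix(c(0, B3[1], C3[1]), c(0, B3[2], C3[2]), 3600 * (0:2))
  expect_equal(nrow(spikeFilter(tr3)), 2)
  # under 3 fixes: unchanged with a warning
  expect_warning(out <- spikeFilter(tr[1:2, ]), "fewer than 3")
  expect_equal(nrow(out), 2)
})

test_that("velocity filter is the greedy forward pass it claims to be", {
  # 1 km in 60 s = 16.7 m/s: retained at vmax 20
  tr <- mkfix(c(0, 1000), 0, c(0, 60))
  expect_equal(nrow(velocityFilter(tr, 20)), 2)
  # 3 km in 60 s = 50 m/s: removed at vmax 40
  tr <- mkfix(c(0, 3000), 0, c(0, 60))
  out <- velocityFilter(tr, 40)
  expect_equal(nrow(out), 1)
  expect_equal(removedFixes(out)$reason, "velocity")
  # randomized tracks match a brute-force enumeration of the greedy rule
  set.seed(42)
  for (case in 1:50) {
    tr <- randomTrack(30)
    vmax <- sample(c(20, 27.8, 40), 1)
    got <- velocityFilter(tr, vmax)
    keep <- 1L
    for (i in 2:nrow(tr)) {
      last <- keep[length(keep)]
      dt <- as.numeric(tr$timestamp[i]) - as.numeric(tr$timestamp[last])
      d <- sqrt((tr$x[i] - tr$x[last])^2 + (tr$y[i] - tr$y[last])^2)
      if (d / dt <= vmax) keep <- c(keep, i)
    }
    expect_equal(got$x, tr$x[keep])
  }
})

test_that("hourly subsampling keeps the earliest fix per deployment-hour", {
  t0 <- as.POSIXct("2016-01-05 17:00:00", tz = "UTC")
  tr <- mkfix(1:4 * 100, 0, c(0, 15, 30, 45) * 60)
  expect_equal(nrow(hourlySubsample(tr)), 1)
  expect_equal(hourlySubsample(tr)$x, 100)
  # 17:59 and 18:01 are different clock hours
  tr <- mkfix(c(1, 2), 0, c(59 * 60, 61 * 60))
  expect_equal(nrow(hourlySubsample(tr)), 2)
  # randomized timestamps match an independent per-hour grouping oracle
  set.seed(7)
  tr <- randomTrack(200)
  got <- hourlySubsample(tr)
  key <- format(tr$timestamp, "%Y-%m-%d %H", tz = "UTC")
  oracle <- do.call(rbind, lapply(split(tr, key), function(g)
    g[which.min(g$timestamp), ]))
  expect_equal(sort(as.numeric(got$timestamp)),
               sort(as.numeric(oracle$timestamp)))
})

test_that("season/daytime selection applies the one-hour twilight margin", {
  d <- as.Date("2016-01-15")
  ss <- sunriseSunset(43, -107.5, d)
  base <- data.frame(deployment_id = "d1", x = 0, y = 0,
                     lon = -107.5, lat = 43, fix_type = "GPS",
                     argos_class = NA_character_)
  fx <- rbind(
    cbind(base, timestamp = ss$sunrise + 1800),   # 30 min after sunrise
    cbind(base, timestamp = ss$solar_noon),       # midday January
    cbind(base, timestamp = ss$sunset - 1800),    # 30 min before sunset
    cbind(base, timestamp = as.POSIXct("2016-03-15 19:00:00", tz = "UTC")),
    cbind(base, timestamp = as.POSIXct("2016-07-15 19:00:00", tz = "UTC")))
  out <- seasonDaytimeFilter(fx)
  expect_equal(nrow(out$winter), 1)
  expect_equal(out$winter$timestamp, ss$solar_noon)
  expect_equal(nrow(out$summer), 1)   # July fix, any hour
  # March fix is in neither seasonal set
  expect_equal(nrow(out$winter) + nrow(out$summer) +
                 nrow(removedFixes(out$winter)), 4)
})

test_that("bout segmentation splits at 48-h gaps and enforces the 28-day minimum", {
  t0 <- as.POSIXct("2016-01-01", tz = "UTC")
  mk <- function(days, offset = 0)
    mkfix(seq_along(days), 0, offset + days * 86400, start = t0)
  # 60 gap-free days -> one bout
  b <- segmentBouts(mk(seq(0, 60, by = 0.25)))
  expect_length(b, 1)
  # 20-day track -> none
  expect_length(segmentBouts(mk(seq(0, 20, by = 0.25))), 0)
  # 30 days + 3-day gap + 30 days -> two bouts
  tr <- mk(c(seq(0, 30, by = 0.25), seq(33, 63, by = 0.25)))
  expect_length(segmentBouts(tr), 2)
})

test_that("residence classification separates dwell from straight transit", {
  t0 <- as.POSIXct("2016-01-01", tz = "UTC")
  # stationary cluster for 10 days: all sedentary
  set.seed(3)
  n <- 240
  cl <- data.frame(deployment_id = "d1", timestamp = t0 + 3600 * (0:(n - 1)),
                   x = rnorm(n, 0, 300), y = rnorm(n, 0, 300))
  out <- rstClassify(cl)
  expect_true(all(out$state == "sedentary"))
  # 300-km straight transit at 15 m/s between two 14-day clusters
  nh <- 14 * 24
  seg1 <- data.frame(x = rnorm(nh, 0, 300), y = rnorm(nh, 0, 300))
  hrs <- ceiling(300000 / (15 * 3600))
  trans <- data.frame(x = seq(0, 300000, length.out = hrs + 1)[-1], y = 0)
  seg2 <- data.frame(x = 300000 + rnorm(nh, 0, 300), y = rnorm(nh, 0, 300))
  tr <- rbind(seg1, trans, seg2)
  tr <- data.frame(deployment_id = "d1",
                   timestamp = t0 + 3600 * seq_len(nrow(tr)), tr)
  out <- rstClassify(tr, radius_m = 30000)
  mid <- nh + seq_len(nrow(trans))
  interior <- mid[trans$x > 40000 & trans$x < 260000]
  expect_true(all(out$state[interior] == "transit"))
  expect_true(all(out$state[1:nh] == "sedentary"))
  expect_error(rstClassify(tr, radius_m = -1), "positive")
})

test_that("RST recovers the generator's sedentary/transit truth labels", {
  cfg <- simConfig(nrow = 100, ncol = 100, res = 4000, smoothing_cells = 8,
                   n_base_per_category = 1, betas = c(wind_uplift_1 = 1),
                   groups = c(adult_res_floater = 3),
                   resettle_days = 10, argos_fraction = 0,
                   outlier_rate = 0, seed = 3)
  sim <- generateTracks(cfg)
  w <- sim$fixes[format(sim$fixes$timestamp, "%m") %in%
                   c("12", "01", "02"), ]
  cl <- do.call(rbind, lapply(segmentBouts(w), rstClassify,
                              radius_m = 30000))
  expect_gt(mean(cl$state == cl$truth_state), 0.8)
})

test_that("two-per-day thinning keeps a separated morning/afternoon pair", {
  d <- as.Date("2016-01-15")
  noon <- solarNoon(-107.5, d)
  base <- data.frame(deployment_id = "d1", x = 0, y = 0, lon = -107.5,
                     lat = 43, fix_type = "GPS",
                     argos_class = NA_character_)
  mk <- function(offsets_h) {
    out <- base[rep(1, length(offsets_h)), ]
    out$timestamp <- noon + offsets_h * 3600
    out
  }
  # 10 morning + 10 afternoon fixes -> exactly 2 retained, >= 1 h apart
  fx <- mk(c(seq(-5, -0.5, length.out = 10), seq(0.5, 5, length.out = 10)))
  out <- thinTwoPerDay(fx, seed = 1)
  expect_equal(nrow(out), 2)
  expect_gte(diff(as.numeric(sort(out$timestamp))), 3600)
  expect_true(out$timestamp[1] < noon && out$timestamp[2] >= noon)
  # afternoon-only day -> 1 retained
  fx2 <- mk(seq(0.5, 4, length.out = 8))
  expect_equal(nrow(thinTwoPerDay(fx2, seed = 1)), 1)
  # no pair separated by 1 h -> 1 retained
  fx3 <- mk(c(-0.2, 0.2))
  expect_equal(nrow(thinTwoPerDay(fx3, seed = 1)), 1)
  # determinism
  expect_identical(thinTwoPerDay(fx, seed = 9), thinTwoPerDay(fx, seed = 9))
})

test_that("train/test split is a seeded partition at the requested fraction", {
  fx <- randomTrack(100)
  sp <- trainTestSplit(fx, 0.75, seed = 5)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  expect_identical(sp, trainTestSplit(fx, 0.75, seed = 5))
  both <- rbind(sp$train, sp$test)
  expect_setequal(as.numeric(both$timestamp), as.numeric(fx$timestamp))
  expect_equal(nrow(merge(sp$train, sp$test)), 0)
})

test_that("filters are idempotent, only remove rows, and account for removals", {
  sim <- smallSim()
  fx <- sim$tracks$fixes
  fx$fix_id <- seq_len(nrow(fx))
  for (flt in list(argosClassFilter,
                   function(f) spikeFilter(f),
                   function(f) velocityFilter(f, 27.8),
                   hourlySubsample)) {
    out1 <- suppressWarnings(flt(fx))
    expect_equal(nrow(fx), nrow(out1) + nrow(removedFixes(out1)))
    # retained rows are unaltered
    expect_identical(out1$x, fx$x[fx$fix_id %in% out1$fix_id])
    expect_identical(out1$timestamp,
                     fx$timestamp[fx$fix_id %in% out1$fix_id])
    out2 <- suppressWarnings(flt(out1))
    expect_equal(nrow(out2), nrow(out1))
    fx <- out1
  }
})
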