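# KDE home ranges, age classes, and the classification cascade.

test_that("95% KDE area of a circular normal cloud matches a numerical-integration oracle", {
  set.seed(12)
  n <- 1000
  x <- rnorm(n, 0, 1000); y <- rnorm(n, 0, 1000)
  hr <- kdeHomeRange(x, y, level = 0.95, smoothing_prop = 0.7)
  # oracle: area of the 95% mass region of the smoothed density, which for
  # a normal sample with normal kernel is ~ bivariate normal with variance
  # sigma^2 + h^2 per axis -> area = pi * chi2(0.95, 2) * s1 * s2
  h <- 0.7 * c(sd(x), sd(y)) * n^(-1 / 6)
  s <- sqrt(c(sd(x), sd(y))^2 + h^2)
  oracle <- pi * qchisq(0.95, 2) * s[1] * s[2] / 1e6
  expect_lt(abs(hr$area_km2 - oracle) / oracle, 0.25)
  # duplicated computation is identical (deterministic)
  hr2 <- kdeHomeRange(x, y)
  expect_identical(hr$area_km2, hr2$area_km2)
  expect_identical(hr$thr, hr2$thr)
  # two clusters 100 km apart exceed the single-cluster area
  hr3 <- kdeHomeRange(c(x, x + 1e5), c(y, y))
  expect_gt(hr3$area_km2, hr$area_km2)
  expect_error(kdeHomeRange(1:3, 1:3), "inadequate")
})

test_that("inside/outside the isopleth agrees with the contour-polygon oracle", {
  set.seed(4)
  x <- rnorm(400, 0, 800); y <- rnorm(400, 0, 800)
  hr <- kdeHomeRange(x, y)
  polys <- homeRangePolygon(hr)
  px <- runif(300, -4000, 4000); py <- runif(300, -4000, 4000)
  got <- insideHomeRange(hr, px, py)
  oracle <- pointInPolygon(px, py, polys)
  # boundary-adjacent points may differ between the density and polygon
  # representations; require near-total agreement
  expect_gt(mean(got == oracle), 0.97)
})

test_that("age classes follow the biological year starting in April", {
  # tagged as nestling July 2015: age 3 in January 2019, 4 in January 2020
  a <- assignAgeClass(as.Date("2015-07-01"), 0, as.Date("2019-01-15"))
  expect_equal(a$age, 3)
  expect_equal(a$age_class, "non-adult")
  a <- assignAgeClass(as.Date("2015-07-01"), 0, as.Date("2020-01-15"))
  expect_equal(a$age, 4)
  expect_equal(a$age_class, "adult")
  # tagged as adult stays adult
  a <- assignAgeClass(as.Date("2015-07-01"), 5, as.Date("2016-01-15"))
  expect_equal(a$age_class, "adult")
  expect_error(assignAgeClass(as.Date(NA), 2, as.Date("2016-01-01")),
               "missing age metadata")
})

test_that("migrants keep all study-area winter fixes regardless of age", {
  sa <- rectPolygon(c(-50000, 50000, -50000, 50000))
  t0 <- as.POSIXct("2016-01-01", tz = "UTC")
  wf <- data.frame(deployment_id = "m1", timestamp = t0 + 1:50 * 3600,
                   x = rnorm(50, 0, 5000), y = rnorm(50, 0, 5000),
                   lon = -107.5, lat = 43)
  sf <- wf; sf$lat <- 60.5; sf$timestamp <- t0 - 180 * 86400 + 1:50 * 3600
  meta <- data.frame(deployment_id = "m1",
                     tag_date = as.Date("2014-07-01"), age_at_tagging = 5,
                     tagged_as_nestling = FALSE, natal_lon = NA,
                     natal_lat = NA, tag_lat = 61)
  res <- classifyAndFilter(meta, wf, sf, sa)
  expect_equal(res$label, "Adult Migrant")
  expect_equal(nrow(res$fixes), 50)
  expect_equal(nrow(res$removed), 0)
})

test_that("the natal-core rule removes only fixes within a year and 3.2 km", {
  sa <- rectPolygon(c(-50000, 50000, -50000, 50000))
  t0 <- as.POSIXct("2016-01-10", tz = "UTC")   # ~6 months after tagging
  proj <- laeaProjection()
  natal <- unprojectXY(proj, 0, 0)
  wf <- data.frame(deployment_id = "n1",
                   timestamp = t0 + 1:2 * 3600,
                   x = c(2000, 5000), y = c(0, 0),
                   lon = -107.5, lat = 43)
  sf <- data.frame(deployment_id = "n1",
                   timestamp = as.POSIXct("2015-07-15", tz = "UTC") +
                     1:30 * 86400,
                   x = rnorm(30, 0, 500), y = rnorm(30, 0, 500),
                   lon = -107.5, lat = 43)
  meta <- data.frame(deployment_id = "n1",
                     tag_date = as.Date("2015-07-01"), age_at_tagging = 0,
                     tagged_as_nestling = TRUE,
                     natal_lon = natal$lon, natal_lat = natal$lat,
                     tag_lat = 43)
  res <- classifyAndFilter(meta, wf, sf, sa, proj)
  expect_equal(res$label, "Non-adult Non-migrant")
  expect_equal(res$fixes$x, 5000)               # 5-km fix retained
  expect_equal(res$removed$x, 2000)             # 2-km fix removed
  expect_equal(res$removed$reason, "natal_core")
})

test_that("territory holders lose exactly the winter fixes inside the summer KDE", {
  set.seed(31)
  sa <- rectPolygon(c(-60000, 60000, -60000, 60000))
  t0 <- as.POSIXct("2016-01-01", tz = "UTC")
  # compact summer range near the origin (territory), ~40% of winter fixes
  # deliberately placed inside it
  sf <- data.frame(deployment_id = "b1",
                   timestamp = as.POSIXct("2015-06-05", tz = "UTC") +
                     seq(0, 80 * 86400, by = 6 * 3600),
                   x = rnorm(321, 0, 2000), y = rnorm(321, 0, 2000),
                   lon = -107.5, lat = 43)
  n_in <- 40; n_out <- 60
  wf <- data.frame(deployment_id = "b1",
                   timestamp = t0 + seq_len(n_in + n_out) * 3600,
                   x = c(rnorm(n_in, 0, 800), rnorm(n_out, 30000, 3000)),
                   y = c(rnorm(n_in, 0, 800), rnorm(n_out, -20000, 3000)),
                   lon = -107.5, lat = 43)
  meta <- data.frame(deployment_id = "b1",
                     tag_date = as.Date("2014-07-01"), age_at_tagging = 6,
                     tagged_as_nestling = FALSE, natal_lon = NA,
                     natal_lat = NA, tag_lat = 43)
  res <- classifyAndFilter(meta, wf, sf, sa)
  expect_equal(res$label, "Adult Non-migrant Territory-holder")
  hr <- kdeHomeRange(sf$x, sf$y)
  expect_lt(hr$area_km2, 200)
  # brute-force point-in-polygon oracle over the isopleth rings
  polys <- homeRangePolygon(hr)
  inside_oracle <- pointInPolygon(wf$x, wf$y, polys)
  expect_setequal(res$removed$x[res$removed$reason == "inside_summer_range"],
                  wf$x[inside_oracle])
  # invariant: no retained fix lies inside the governing summer KDE
  expect_false(any(insideHomeRange(hr, res$fixes$x, res$fixes$y)))
})

test_that("floaters (large summer ranges) keep all their winter fixes", {
  set.seed(8)
  sa <- rectPolygon(c(-60000, 60000, -60000, 60000))
  sf <- data.frame(deployment_id = "f1",
                   timestamp = as.POSIXct("2015-06-05", tz = "UTC") +
                     seq(0, 80 * 86400, by = 6 * 3600),
                   x = rnorm(321, 0, 12000), y = rnorm(321, 0, 12000),
                   lon = -107.5, lat = 43)
  wf <- data.frame(deployment_id = "f1",
                   timestamp = as.POSIXct("2016-01-01", tz = "UTC") +
                     1:80 * 3600,
                   x = rnorm(80, 0, 20000), y = rnorm(80, 0, 20000),
                   lon = -107.5, lat = 43)
  meta <- data.frame(deployment_id = "f1",
                     tag_date = as.Date("2014-07-01"), age_at_tagging = 7,
                     tagged_as_nestling = FALSE, natal_lon = NA,
                     natal_lat = NA, tag_lat = 43)
  res <- classifyAndFilter(meta, wf, sf, sa)
  expect_gte(kdeHomeRange(sf$x, sf$y)$area_km2, 200)
  expect_equal(res$label, "Adult Non-migrant Non-territorial")
  expect_equal(nrow(res$fixes), 80)
})

test_that("adults with inadequate summer data near the study area are removed entirely", {
  sa <- rectPolygon(c(-60000, 60000, -60000, 60000))
  sf <- data.frame(deployment_id = "x1",
                   timestamp = as.POSIXct("2015-07-01", tz = "UTC") +
                     1:10 * 3600,      # 10 locations, < 30 days
                   x = rnorm(10, 0, 2000), y = rnorm(10, 0, 2000),
                   lon = -107.5, lat = 43)
  wf <- data.frame(deployment_id = "x1",
                   timestamp = as.POSIXct("2016-01-01", tz = "UTC") +
                     1:20 * 3600,
                   x = rnorm(20, 0, 5000), y = rnorm(20, 0, 5000),
                   lon = -107.5, lat = 43)
  meta <- data.frame(deployment_id = "x1",
                     tag_date = as.Date("2014-07-01"), age_at_tagging = 5,
                     tagged_as_nestling = FALSE, natal_lon = NA,
                     natal_lat = NA, tag_lat = 43)
  res <- classifyAndFilter(meta, wf, sf, sa)
  expect_equal(res$removed_individual, "inadequate_summer_data")
  expect_equal(nrow(res$fixes), 0)
  # contradictory metadata is an error
  meta$tagged_as_nestling <- TRUE
  expect_error(classifyAndFilter(meta, wf, sf, sa), "contradictory")
})

test_that("the cascade recovers at least 95% of generator truth labels", {
  sim <- smallSim()
  f <- hourlySubsample(velocityFilter(spikeFilter(argosClassFilter(
    sim$tracks$fixes))))
  seas <- seasonDaytimeFilter(f)
  cls <- classifyDeployments(seas$winter, seas$summer,
                             sim$tracks$deployments,
                             studyAreaPolygon(sim$cfg), sim$cfg$proj)
  truth_label <- c(adult_migrant = "Adult Migrant",
                   adult_res_territorial = "Adult Non-migrant Territory-holder",
                   adult_res_floater = "Adult Non-migrant Non-territorial",
                   nonadult_resident = "Non-adult Non-migrant",
                   nonadult_migrant = "Non-adult Migrant")
  expected <- truth_label[sim$tracks$deployments$truth_group]
  got <- cls$labels$label[match(sim$tracks$deployments$deployment_id,
                                cls$labels$deployment_id)]
  expect_gte(mean(got == expected, na.rm = TRUE), 0.95)
  # every individual receives exactly one label or one removal reason
  expect_true(all(!is.na(cls$labels$label) |
                    !is.na(cls$labels$removed_individual)))
})
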