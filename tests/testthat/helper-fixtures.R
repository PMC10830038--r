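# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env()

# A small synthetic world with all five life-history groups, shared across
# test files to keep the suite fast.
smallSim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- simConfig(
      nrow = 60, ncol = 60, smoothing_cells = 6, n_base_per_category = 1,
      betas = c(wind_uplift_1 = 1.2),
      groups = c(adult_migrant = 2, adult_res_territorial = 3,
                 adult_res_floater = 2, nonadult_resident = 3,
                 nonadult_migrant = 2),
      outlier_rate = 0.002, seed = 11)
    stack <- generateCovariateStack(cfg)
    truth <- trueIntensity(stack, cfg$betas)
    .fixture_env$sim <- list(cfg = cfg, stack = stack, truth = truth,
                             tracks = generateTracks(cfg, truth))
  }
  .fixture_env$sim
}

# Independent ephemeris oracle: Meeus-style solar position (Julian
# centuries, mean anomaly, ecliptic longitude, obliquity) — a different
# formulation than the packaged Fourier-series method.
meeusSunriseSunset <- function(lat, lon, date) {
  jd <- as.numeric(as.Date(date)) + 2440587.5 + 0.5  # noon UTC
  Tc <- (jd - 2451545) / 36525
  d2r <- pi / 180
  L0 <- (280.46646 + 36000.76983 * Tc + 0.0003032 * Tc^2) %% 360
  M <- 357.52911 + 35999.05029 * Tc - 0.0001537 * Tc^2
  e <- 0.016708634 - 0.000042037 * Tc
  C <- (1.914602 - 0.004817 * Tc) * sin(M * d2r) +
    (0.019993 - 0.000101 * Tc) * sin(2 * M * d2r) +
    0.000289 * sin(3 * M * d2r)
  trueL <- L0 + C
  omega <- 125.04 - 1934.136 * Tc
  lambda <- trueL - 0.00569 - 0.00478 * sin(omega * d2r)
  eps <- 23.439291 - 0.0130042 * Tc + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r))
  y <- tan(eps / 2 * d2r)^2
  eqt <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * e * sin(M * d2r) +
                      4 * e * y * sin(M * d2r) * cos(2 * L0 * d2r) -
                      0.5 * y^2 * sin(4 * L0 * d2r) -
                      1.25 * e^2 * sin(2 * M * d2r))
  cosha <- (cos(90.833 * d2r) - sin(lat * d2r) * sin(decl)) /
    (cos(lat * d2r) * cos(decl))
  if (abs(cosha) > 1) return(list(sunrise = NA, sunset = NA))
  ha <- acos(cosha) / d2r
  day0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  list(sunrise = day0 + 60 * (720 - 4 * (lon + ha) - eqt),
       sunset = day0 + 60 * (720 - 4 * (lon - ha) - eqt))
}

# Random telemetry track generator for randomized filter-oracle cases.
randomTrack <- function(n, dep = "d1", step_sd = 2000,
                        start = as.POSIXct("2016-01-01 16:00:00",
                                           tz = "UTC")) {
  dt <- cumsum(sample(c(600, 1800, 3600, 7200), n, replace = TRUE))
  data.frame(deployment_id = dep, timestamp = start + dt,
             x = cumsum(rnorm(n, 0, step_sd)),
             y = cumsum(rnorm(n, 0, step_sd)),
             lon = -107.5 + rnorm(n, 0, 0.05),
             lat = 43 + rnorm(n, 0, 0.05),
             fix_type = "GPS", argos_class = NA_character_,
             stringsAsFactors = FALSE)
}

# Nested-grid brute-force maximizer of the penalized maxent objective
# (independent of the coordinate-descent path); works for <= 3 features.
gridMaximizeObjective <- function(obj, p, width = 6, levels = 12,
                                  points = 13) {
  ctr <- rep(0, p)
  w <- width
  for (r in seq_len(levels)) {
    axes <- lapply(seq_len(p), function(j)
      seq(ctr[j] - w, ctr[j] + w, length.out = points))
    g <- as.matrix(expand.grid(axes))
    vals <- apply(g, 1, obj)
    ctr <- as.numeric(g[which.max(vals), ])
    w <- w * 2 / (points - 1)
  }
  ctr
}
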