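# Synthetic world generator: smooth covariate fields, a known log-linear
# intensity surface, and telemetry tracks for the five life-history groups,
# with GPS/Argos error and injected spike outliers. Everything is a pure
# function of the configuration (including its seed).

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so calls are reproducible without
#' disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.CATEGORIES <- c("climate_weather", "vegetation_landcover", "developed",
                 "topography", "wind_uplift")

#' Simulation configuration
#'
#' Defines the synthetic study system: grid geometry, covariate fields, the
#' true log-linear intensity coefficients, per-group individual counts,
#' tracking cadence and seasons, and the location-error regime. The seed
#' fully determines all generator outputs.
#'
#' Group counts default to the deployment counts of the study design the
#' generator emulates (54 adult migrants, 60 adult resident territory
#' holders, 44 adult resident floaters, 74 non-adult residents, 36 non-adult
#' migrants); tests and examples pass smaller counts explicitly.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param res cell size (m); default 120.
#' @param proj a [laeaProjection()] giving the equal-area CRS.
#' @param n_base_per_category continuous base variables per category.
#' @param smoothing_cells Gaussian smoothing length (sd, in cells) of the
#'   covariate fields.
#' @param category_mix within-category mixing weight in [0,1) creating
#'   multicollinearity among layers of a category.
#' @param n_ecoregions number of classes of the categorical ecoregion layer.
#' @param betas named numeric vector of true coefficients over a subset of
#'   covariate layer names (layer names are `<category>_<i>`).
#' @param groups named integer vector of individuals per life-history group;
#'   names must be among `adult_migrant`, `adult_res_territorial`,
#'   `adult_res_floater`, `nonadult_resident`, `nonadult_migrant`.
#' @param fixes_per_hour fix cadence.
#' @param winter,summer character date ranges `c(from, to)` (UTC).
#' @param outlier_rate fraction of fixes displaced into spike outliers.
#' @param outlier_dist_m displacement distance of injected spikes (m).
#' @param argos_fraction fraction of fixes that are Argos rather than GPS.
#' @param argos_class_mix named mix over Argos classes.
#' @param step_sd sedentary step scale (m).
#' @param step_rho autocorrelation of sedentary displacements.
#' @param resettle_days mean days between intensity-weighted resettlements.
#' @param bias_weight exponent on the true intensity when sampling
#'   settlement centers (larger = stronger attraction).
#' @param transit_speed speed of directed transit movements (m/s).
#' @param transit_min_km minimum center separation (km) that generates a
#'   labelled transit leg.
#' @param natal_tag_fraction share of non-adult residents tagged as
#'   nestlings with a known natal site.
#' @param seed integer master seed.
#' @return An object of class `sim_config`.
#' @export
simConfig <- function(nrow = 600, ncol = 600, res = 120,
                      proj = laeaProjection(),
                      n_base_per_category = 2,
                      smoothing_cells = 10,
                      category_mix = 0.3,
                      n_ecoregions = 3,
                      betas = c(wind_uplift_1 = 1.2,
                                vegetation_landcover_1 = 0.8,
                                topography_1 = -0.6),
                      groups = c(adult_migrant = 54,
                                 adult_res_territorial = 60,
                                 adult_res_floater = 44,
                                 nonadult_resident = 74,
                                 nonadult_migrant = 36),
                      fixes_per_hour = 1,
                      winter = c("2015-12-01", "2016-02-28"),
                      summer = c("2015-06-01", "2015-08-31"),
                      outlier_rate = 0.002,
                      outlier_dist_m = 10000,
                      argos_fraction = 0.09,
                      argos_class_mix = c("3" = 0.5, "2" = 0.3, "1" = 0.2),
                      step_sd = 500, step_rho = 0.5,
                      resettle_days = 5, bias_weight = 1,
                      transit_speed = 15, transit_min_km = 5,
                      natal_tag_fraction = 0.5,
                      seed = 1) {
  if (nrow <= 0 || ncol <= 0)
    stop("grid dimensions must be positive", call. = FALSE)
  if (res <= 0) stop("resolution must be positive", call. = FALSE)
  if (length(betas) == 0 || all(betas == 0))
    stop("at least one covariate must have a nonzero true coefficient",
         call. = FALSE)
  known <- c("adult_migrant", "adult_res_territorial", "adult_res_floater",
             "nonadult_resident", "nonadult_migrant")
  if (!all(names(groups) %in% known))
    stop("unknown group name(s): ",
         paste(setdiff(names(groups), known), collapse = ", "),
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d x %d grid at %g m, %d groups, seed %d\n",
              x$nrow, x$ncol, x$res, length(x$groups), x$seed))
  invisible(x)
}

# Gaussian smoothing of a matrix by FFT (circular boundary). sigma in cells.
.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  wr <- pmin(0:(nr - 1), nr - 0:(nr - 1))  # wrapped lags
  wc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kr <- exp(-0.5 * (wr / sigma)^2)
  kc <- exp(-0.5 * (wc / sigma)^2)
  k <- outer(kr, kc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

.standardize <- function(m) (m - mean(m)) / stats::sd(as.vector(m))

#' Generate the synthetic covariate stack
#'
#' One smooth, spatially autocorrelated field per continuous base variable
#' (Gaussian-filtered white noise, standardized to mean 0, sd 1), tagged
#' with a category; within-category mixing of a shared field induces
#' realistic multicollinearity. A categorical ecoregion layer with
#' `n_ecoregions` classes is appended.
#'
#' @param config a [simConfig()].
#' @return A [CovariateStack-class] centered on the projection origin.
#' @export
generateCovariateStack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withSeed(config$seed, {
    nr <- config$nrow; nc <- config$ncol
    layers <- list(); meta <- NULL
    for (cat in .CATEGORIES) {
      shared <- .gaussSmooth(matrix(rnorm(nr * nc), nr, nc),
                             config$smoothing_cells)
      for (i in seq_len(config$n_base_per_category)) {
        own <- .gaussSmooth(matrix(rnorm(nr * nc), nr, nc),
                            config$smoothing_cells)
        mix <- config$category_mix
        # positive-shifted unit-variance fields: keeps exp(beta . x) well
        # scaled and makes mean-ratio screening meaningful
        f <- 3 + .standardize(sqrt(1 - mix) * .standardize(own) +
                                sqrt(mix) * .standardize(shared))
        nm <- sprintf("%s_%d", cat, i)
        layers[[nm]] <- gridRaster(
          f, xll = -nc / 2 * config$res, yll = -nr / 2 * config$res,
          res = config$res, crs = "laea")
        meta <- rbind(meta, data.frame(
          name = nm, base = nm, category = cat,
          extent_m = config$res, statistic = "none", categorical = FALSE))
      }
    }
    eco_field <- .gaussSmooth(matrix(rnorm(nr * nc), nr, nc),
                              config$smoothing_cells * 2)
    cuts <- quantile(eco_field, probs = seq(0, 1,
                                            length.out = config$n_ecoregions + 1))
    eco <- matrix(as.numeric(cut(eco_field, breaks = cuts,
                                 include.lowest = TRUE)), nr, nc)
    layers[["ecoregion"]] <- gridRaster(
      eco, xll = -nc / 2 * config$res, yll = -nr / 2 * config$res,
      res = config$res, crs = "laea")
    meta <- rbind(meta, data.frame(
      name = "ecoregion", base = "ecoregion", category = "ecoregion",
      extent_m = config$res, statistic = "none", categorical = TRUE))
    covariateStack(layers, meta)
  })
}

#' True relative intensity of use
#'
#' Cell value proportional to `exp(sum_j beta_j x_j)`, normalized to sum
#' to 1 over the grid (an inhomogeneous Poisson point-process intensity up
#' to total abundance).
#'
#' @param stack a [CovariateStack-class].
#' @param betas named coefficients over a subset of layer names.
#' @return An [IntensitySurface-class] with `scaling = "sum1"`.
#' @export
trueIntensity <- function(stack, betas) {
  missing <- setdiff(names(betas), names(stack@layers))
  if (length(missing))
    stop("betas reference unknown layers: ",
         paste(missing, collapse = ", "), call. = FALSE)
  g <- stack@layers[[1]]
  eta <- matrix(0, nrow(g@values), ncol(g@values))
  for (nm in names(betas))
    eta <- eta + betas[[nm]] * stack@layers[[nm]]@values
  e <- exp(eta)
  if (any(!is.finite(e)))
    stop("intensity overflow: exp(beta . x) is non-finite; ",
         "center/rescale the covariates or shrink the coefficients",
         call. = FALSE)
  new("IntensitySurface", values = e / sum(e), xll = g@xll, yll = g@yll,
      res = g@res, crs = g@crs, scaling = "sum1", area = "study")
}

#' Sample presence points from an intensity surface
#'
#' Draws i.i.d. points from the point process: cells are sampled with
#' probability proportional to intensity, then positions jittered uniformly
#' within the cell.
#'
#' @param surface an [IntensitySurface-class] (any positive scaling).
#' @param n number of points.
#' @param seed integer seed.
#' @return data.frame with `x`, `y` (m).
#' @export
samplePresence <- function(surface, n, seed = 1) {
  withSeed(seed, {
    cc <- cellCenters(surface)
    p <- cc$value
    p[!is.finite(p)] <- 0
    idx <- sample.int(nrow(cc), n, replace = TRUE, prob = p)
    r <- surface@res
    data.frame(x = cc$x[idx] + runif(n, -r / 2, r / 2),
               y = cc$y[idx] + runif(n, -r / 2, r / 2))
  })
}

# Sample settlement centers proportional to intensity^w (cells + jitter).
.sampleCenters <- function(surface, n, w) {
  cc <- cellCenters(surface)
  p <- pmax(cc$value, 0)^w
  idx <- sample.int(nrow(cc), n, replace = TRUE, prob = p)
  r <- surface@res
  cbind(cc$x[idx] + runif(n, -r / 2, r / 2),
        cc$y[idx] + runif(n, -r / 2, r / 2))
}

# OU-style wander around a center: vectorized recursive filter.
.ouTrack <- function(center, n, step_sd, rho) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  ex <- stats::filter(rnorm(n, 0, step_sd), rho, "recursive")
  ey <- stats::filter(rnorm(n, 0, step_sd), rho, "recursive")
  cbind(center[1] + as.numeric(ex), center[2] + as.numeric(ey))
}

# Simulate one season of movement inside the study grid: settlement centers
# sampled from the intensity surface, OU wander within settlements, directed
# transit legs between distant settlements. Returns x, y, state per fix time.
.simulateSeason <- function(times, surface, cfg, n_centers) {
  n <- length(times)
  centers <- .sampleCenters(surface, n_centers, cfg$bias_weight)
  # split fix indices into consecutive settlement blocks
  block <- sort(rep_len(seq_len(n_centers), n))
  x <- numeric(n); y <- numeric(n)
  state <- rep("sedentary", n)
  pos <- centers[1, ]
  for (b in seq_len(n_centers)) {
    ii <- which(block == b)
    if (!length(ii)) next
    target <- centers[b, ]
    d <- sqrt(sum((pos - target)^2))
    if (b > 1 && d > cfg$transit_min_km * 1000) {
      # directed transit leg at transit_speed, consuming leading fixes
      dt <- as.numeric(diff(c(times[max(1, ii[1] - 1)], times[ii])),
                       units = "secs")
      step <- cfg$transit_speed * dt
      trav <- cumsum(step)
      k <- sum(trav < d)              # fixes spent in transit
      k <- min(k, length(ii) - 1)
      if (k > 0) {
        u <- (target - pos) / d
        for (j in seq_len(k)) {
          frac <- trav[j] / d
          x[ii[j]] <- pos[1] + u[1] * frac * d +
            rnorm(1, 0, cfg$step_sd / 2)
          y[ii[j]] <- pos[2] + u[2] * frac * d +
            rnorm(1, 0, cfg$step_sd / 2)
          state[ii[j]] <- "transit"
        }
        ii <- ii[-seq_len(k)]
      }
    }
    w <- .ouTrack(target, length(ii), cfg$step_sd, cfg$step_rho)
    x[ii] <- w[, 1]; y[ii] <- w[, 2]
    pos <- c(x[max(ii)], y[max(ii)])
  }
  data.frame(time = times, x = x, y = y, state = state)
}

.seasonTimes <- function(range, cfg) {
  from <- as.POSIXct(paste(range[1], "00:00:00"), tz = "UTC")
  to <- as.POSIXct(paste(range[2], "23:59:59"), tz = "UTC")
  seq(from, to, by = 3600 / cfg$fixes_per_hour)
}

#' Generate synthetic telemetry tracks for all life-history groups
#'
#' For each simulated individual a biased correlated random walk attracted
#' to high true intensity generates winter fixes inside the study grid;
#' summer fixes are generated around a northern center (migrants; latitude
#' above 58.25 N), a compact territory center (resident territory holders;
#' summer range well under 200 km2), or a diffuse range (floaters; over
#' 200 km2). A configured fraction of fixes is displaced by class-specific
#' Argos error, and spike outliers are injected at the configured rate.
#'
#' @param config a [simConfig()].
#' @param truth the output of [trueIntensity()] for the configured stack,
#'   or `NULL` to generate it internally.
#' @return list with `fixes` (telemetry data.frame including truth
#'   annotations `truth_state`, `truth_group`), `deployments` (metadata:
#'   tag date, age at tagging, nestling flag, natal coordinates, truth
#'   group), and `truth` (the intensity surface used).
#' @export
generateTracks <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (sum(config$groups) == 0)
    stop("zero individuals in every group", call. = FALSE)
  if (is.null(truth)) {
    stack <- generateCovariateStack(config)
    truth <- trueIntensity(stack, config$betas)
  }
  proj <- config$proj
  withSeed(config$seed + 1L, {
    fixes <- list(); deps <- list()
    summer_start <- as.Date(config$summer[1])
    id <- 0L
    for (grp in names(config$groups)) {
      for (k in seq_len(config$groups[[grp]])) {
        id <- id + 1L
        dep <- sprintf("dep%03d", id)
        migrant <- grp %in% c("adult_migrant", "nonadult_migrant")
        adult <- grp %in% c("adult_migrant", "adult_res_territorial",
                            "adult_res_floater")
        nestling <- grp == "nonadult_resident" &&
          runif(1) < config$natal_tag_fraction
        # ages are chosen so the group's age class holds through the study
        # winter (biological year starting in April)
        if (nestling) {
          age_tag <- 0L
          tag_date <- summer_start + 30          # tagged in the study summer
        } else if (adult) {
          age_tag <- sample(4:10, 1)
          tag_date <- summer_start - 365 * sample(1:2, 1)
        } else {
          age_tag <- sample(1:2, 1)              # 2-3 years old in winter
          tag_date <- summer_start - 365
        }
        natal <- c(NA_real_, NA_real_)
        # winter inside the study grid
        wt <- .seasonTimes(config$winter, config)
        n_centers <- max(1L, round(
          as.numeric(diff(range(wt)), units = "days") / config$resettle_days))
        wtr <- .simulateSeason(wt, truth, config, n_centers)
        wll <- unprojectXY(proj, wtr$x, wtr$y)
        # summer
        st <- .seasonTimes(config$summer, config)
        if (migrant) {
          sc_lon <- runif(1, -125, -110); sc_lat <- runif(1, 60, 64)
          sproj <- laeaProjection(sc_lon, sc_lat)
          w <- .ouTrack(c(0, 0), length(st), 1000, config$step_rho)
          sll0 <- unprojectXY(sproj, w[, 1], w[, 2])
          pxy <- projectLonLat(proj, sll0$lon, sll0$lat)
          sx <- pxy$x; sy <- pxy$y
          tag_lat <- sc_lat
        } else {
          step <- switch(grp,
                         adult_res_territorial = 500,
                         adult_res_floater = 5000,
                         500)
          ctr <- .sampleCenters(truth, 1, config$bias_weight)[1, ]
          w <- .ouTrack(ctr, length(st), step, config$step_rho)
          sx <- w[, 1]; sy <- w[, 2]
          if (nestling) natal <- ctr
          tag_lat <- unprojectXY(proj, ctr[1], ctr[2])$lat
        }
        sll <- unprojectXY(proj, sx, sy)
        df <- data.frame(
          deployment_id = dep,
          timestamp = c(st, wt),
          x = c(sx, wtr$x), y = c(sy, wtr$y),
          lon = c(sll$lon, wll$lon), lat = c(sll$lat, wll$lat),
          truth_state = c(rep("sedentary", length(st)), wtr$state),
          truth_group = grp, stringsAsFactors = FALSE)
        df <- df[df$timestamp >= as.POSIXct(paste(tag_date, "00:00:00"),
                                            tz = "UTC"), ]
        df <- df[order(df$timestamp), ]
        fixes[[dep]] <- df
        natal_ll <- if (all(is.finite(natal)))
          unprojectXY(proj, natal[1], natal[2]) else
            data.frame(lon = NA_real_, lat = NA_real_)
        deps[[dep]] <- data.frame(
          deployment_id = dep, tag_date = tag_date,
          age_at_tagging = age_tag, tagged_as_nestling = nestling,
          natal_lon = natal_ll$lon, natal_lat = natal_ll$lat,
          tag_lat = tag_lat, truth_group = grp, stringsAsFactors = FALSE)
      }
    }
    fx <- do.call(rbind, fixes)
    rownames(fx) <- NULL
    n <- nrow(fx)
    # fix source and Argos displacement
    is_argos <- runif(n) < config$argos_fraction
    cls <- rep(NA_character_, n)
    cls[is_argos] <- sample(names(config$argos_class_mix), sum(is_argos),
                            replace = TRUE, prob = config$argos_class_mix)
    radii <- list("3" = c(0, 250), "2" = c(250, 500), "1" = c(500, 1500))
    for (cl in names(radii)) {
      ii <- which(!is.na(cls) & cls == cl)
      if (!length(ii)) next
      r <- runif(length(ii), radii[[cl]][1], radii[[cl]][2])
      th <- runif(length(ii), 0, 2 * pi)
      fx$x[ii] <- fx$x[ii] + r * cos(th)
      fx$y[ii] <- fx$y[ii] + r * sin(th)
    }
    fx$fix_type <- ifelse(is_argos, "Argos", "GPS")
    fx$argos_class <- cls
    # spike outliers: large isotropic displacement of interior fixes
    out <- runif(n) < config$outlier_rate
    out[c(1, n)] <- FALSE
    fx$truth_outlier <- out
    if (any(out)) {
      th <- runif(sum(out), 0, 2 * pi)
      fx$x[out] <- fx$x[out] + config$outlier_dist_m * cos(th)
      fx$y[out] <- fx$y[out] + config$outlier_dist_m * sin(th)
    }
    moved <- is_argos | out
    if (any(moved)) {
      ll <- unprojectXY(proj, fx$x[moved], fx$y[moved])
      fx$lon[moved] <- ll$lon; fx$lat[moved] <- ll$lat
    }
    dp <- do.call(rbind, deps); rownames(dp) <- NULL
    list(fixes = fx, deployments = dp, truth = truth)
  })
}

#' Study-area polygon of a simulation
#'
#' The rectangular extent of the configured grid, as a ring in projected
#' meters.
#' @param config a [simConfig()].
#' @export
studyAreaPolygon <- function(config) {
  ext <- c(-config$ncol / 2 * config$res, config$ncol / 2 * config$res,
           -config$nrow / 2 * config$res, config$nrow / 2 * config$res)
  rectPolygon(ext)
}
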