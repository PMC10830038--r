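# Telemetry proofing and selection: Argos class screening, spike and
# velocity filters, hourly standardization, season/daytime selection via
# solar geometry, bout segmentation, residence-in-space-and-time behavioural
# classification, two-per-day thinning, and the train/test split.
#
# All filters only ever remove rows; coordinates and timestamps are never
# altered. Each returns the retained fixes with a `removed` attribute
# (data.frame of dropped rows plus a `reason` column) so that
# count(in) == count(out) + nrow(removed).

#' Default filtering parameters
#'
#' Spike rules are (interior angle, minimum leg length) pairs: a fix is a
#' spike when its turn angle is below the angle and both adjacent segments
#' exceed the length. Candidate velocity thresholds are 20, 27.8 and 40 m/s
#' with 27.8 as the default working value.
#'
#' @export
filterParams <- function() {
  list(spike_rules = data.frame(angle_deg = c(15, 25),
                                min_leg_m = c(2500, 5000)),
       velocity_candidates = c(20, 27.8, 40),
       vmax = 27.8,
       winter_months = c(12, 1, 2),
       summer_months = 6:8,
       daytime_margin_h = 1,
       rst_radius_m = 30000,
       rst_radius_candidates_m = c(6, 10.5, 15, 22.5, 30) * 1000,
       bout_min_days = 28,
       bout_max_gap_h = 48,
       thin_min_sep_h = 1,
       train_fraction = 0.75)
}

.attachRemoved <- function(kept, removed_rows, reason) {
  if (nrow(removed_rows)) removed_rows$reason <- reason
  else removed_rows$reason <- character(0)
  attr(kept, "removed") <- removed_rows
  kept
}

#' Removed-fix log of a filter result
#'
#' @param fixes the result of a filter.
#' @export
removedFixes <- function(fixes) {
  r <- attr(fixes, "removed")
  if (is.null(r)) stop("no removal log attached", call. = FALSE)
  r
}

.perDeployment <- function(fixes, fn, ...) {
  parts <- split(fixes, fixes$deployment_id)
  outs <- lapply(parts, fn, ...)
  kept <- do.call(rbind, outs)
  removed <- do.call(rbind, lapply(outs, attr, "removed"))
  rownames(kept) <- NULL
  if (!is.null(removed)) rownames(removed) <- NULL
  attr(kept, "removed") <- removed
  kept
}

#' Argos location-class filter (proofing)
#'
#' GPS fixes are retained; Argos fixes are retained only in location
#' classes 3, 2 and 1 (estimated error radii under 250 m, 250-500 m and
#' 500-1500 m).
#'
#' @param fixes telemetry data.frame with `fix_type` and `argos_class`.
#' @return retained fixes (removal log in the `removed` attribute).
#' @export
argosClassFilter <- function(fixes) {
  bad_src <- !fixes$fix_type %in% c("GPS", "Argos")
  if (any(bad_src))
    stop("unknown fix source: ",
         paste(unique(fixes$fix_type[bad_src]), collapse = ", "),
         call. = FALSE)
  keep <- fixes$fix_type == "GPS" |
    (fixes$fix_type == "Argos" & !is.na(fixes$argos_class) &
       fixes$argos_class %in% c("3", "2", "1"))
  .attachRemoved(fixes[keep, , drop = FALSE],
                 fixes[!keep, , drop = FALSE], "argos_class")
}

.turnAngles <- function(x, y) {
  # interior angle (degrees) at each interior vertex, with leg lengths
  n <- length(x)
  ax <- x[1:(n - 2)] - x[2:(n - 1)]; ay <- y[1:(n - 2)] - y[2:(n - 1)]
  bx <- x[3:n] - x[2:(n - 1)]; by <- y[3:n] - y[2:(n - 1)]
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2)
  cosang <- (ax * bx + ay * by) / pmax(la * lb, 1e-12)
  list(angle = acos(pmin(1, pmax(-1, cosang))) * 180 / pi,
       leg_in = la, leg_out = lb)
}

#' Spike filter (proofing)
#'
#' Removes out-and-back location spikes: an interior fix whose turn angle
#' is under 15 degrees with both adjacent legs over 2500 m, or under 25
#' degrees with both legs over 5000 m. Re-applied until no spike remains.
#' Geometry is computed in the projected plane.
#'
#' @param fixes telemetry data.frame, time-ordered within deployment, with
#'   projected `x`, `y`.
#' @param rules data.frame of (angle_deg, min_leg_m) pairs.
#' @return retained fixes with removal log.
#' @export
spikeFilter <- function(fixes, rules = filterParams()$spike_rules) {
  .perDeployment(fixes, function(tr) {
    removed <- tr[0, , drop = FALSE]
    if (nrow(tr) < 3) {
      warning("fewer than 3 fixes; spike filter returns track unchanged")
      return(.attachRemoved(tr, removed, "spike"))
    }
    repeat {
      n <- nrow(tr)
      if (n < 3) break
      g <- .turnAngles(tr$x, tr$y)
      is_spike <- rep(FALSE, n)
      for (r in seq_len(nrow(rules)))
        is_spike[2:(n - 1)] <- is_spike[2:(n - 1)] |
          (g$angle < rules$angle_deg[r] &
             g$leg_in > rules$min_leg_m[r] & g$leg_out > rules$min_leg_m[r])
      if (!any(is_spike)) break
      # drop non-adjacent spikes in one pass (adjacent ones re-tested next)
      drop <- logical(n)
      last <- -2L
      for (i in which(is_spike)) {
        if (i - last > 1L) { drop[i] <- TRUE; last <- i }
      }
      removed <- rbind(removed, tr[drop, , drop = FALSE])
      tr <- tr[!drop, , drop = FALSE]
    }
    .attachRemoved(tr, removed, "spike")
  })
}

#' Velocity filter (proofing)
#'
#' Greedy forward pass: a fix implying a sustained speed above `vmax` from
#' the previous retained fix is removed. Duplicate timestamps keep the
#' first fix.
#'
#' @param fixes time-ordered telemetry data.frame with projected `x`, `y`.
#' @param vmax maximum sustained speed (m/s).
#' @return retained fixes with removal log.
#' @export
velocityFilter <- function(fixes, vmax = filterParams()$vmax) {
  .perDeployment(fixes, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(.attachRemoved(tr, tr[0, , drop = FALSE], "velocity"))
    keep <- logical(n); keep[1] <- TRUE
    last <- 1L
    dup_warned <- FALSE
    for (i in 2:n) {
      dt <- as.numeric(tr$timestamp[i]) - as.numeric(tr$timestamp[last])
      if (dt <= 0) {
        if (!dup_warned) {
          warning("duplicate timestamps in deployment ",
                  tr$deployment_id[1], "; retaining the first fix")
          dup_warned <- TRUE
        }
        next
      }
      d <- sqrt((tr$x[i] - tr$x[last])^2 + (tr$y[i] - tr$y[last])^2)
      if (d / dt <= vmax) { keep[i] <- TRUE; last <- i }
    }
    .attachRemoved(tr[keep, , drop = FALSE], tr[!keep, , drop = FALSE],
                   "velocity")
  })
}

#' Hourly subsampling (temporal standardization)
#'
#' At most one fix per deployment per UTC clock-hour; the earliest fix in
#' each hour is retained.
#'
#' @param fixes time-ordered telemetry data.frame.
#' @return retained fixes with removal log.
#' @export
hourlySubsample <- function(fixes) {
  hour_key <- format(fixes$timestamp, "%Y-%m-%d %H", tz = "UTC")
  key <- paste(fixes$deployment_id, hour_key)
  ord <- order(fixes$deployment_id, fixes$timestamp)
  first <- !duplicated(key[ord])
  keep <- logical(nrow(fixes))
  keep[ord] <- first
  .attachRemoved(fixes[keep, , drop = FALSE],
                 fixes[!keep, , drop = FALSE], "hourly_subsample")
}

#' Season and daytime selection
#'
#' Splits fixes into the winter analysis set (December-February, daytime
#' only: at least `margin_h` hours after sunrise and before sunset at the
#' fix location and date) and the summer set (June-August, all hours, kept
#' for home-range estimation). Fixes in other months, winter fixes at night
#' or within the margin, and polar-condition fixes are removed.
#'
#' @param fixes telemetry data.frame with `lon`, `lat`, `timestamp`.
#' @param params [filterParams()].
#' @return list with `winter` and `summer` data.frames; the `winter`
#'   element carries the removal log for the winter-season rule.
#' @export
seasonDaytimeFilter <- function(fixes, params = filterParams()) {
  mon <- as.integer(format(fixes$timestamp, "%m", tz = "UTC"))
  in_winter <- mon %in% params$winter_months
  in_summer <- mon %in% params$summer_months
  summer <- fixes[in_summer, , drop = FALSE]
  wf <- fixes[in_winter, , drop = FALSE]
  if (nrow(wf)) {
    ss <- sunriseSunset(wf$lat, wf$lon, as.Date(wf$timestamp, tz = "UTC"))
    m <- params$daytime_margin_h * 3600
    day <- !is.na(ss$sunrise) & !is.na(ss$sunset) &
      wf$timestamp >= ss$sunrise + m & wf$timestamp <= ss$sunset - m
  } else day <- logical(0)
  winter <- .attachRemoved(wf[day, , drop = FALSE],
                           wf[!day, , drop = FALSE], "night_or_twilight")
  list(winter = winter, summer = summer)
}

#' Segment a track into tracking bouts
#'
#' Splits each deployment at gaps over `max_gap_h` hours and keeps only
#' segments spanning at least `min_days` days. Discontinuous segments of
#' one individual are returned as separate bouts.
#'
#' @param fixes time-ordered telemetry data.frame.
#' @param min_days minimum bout span (days).
#' @param max_gap_h maximum allowed gap (hours).
#' @return list of data.frames, each with a `bout_id` column.
#' @export
segmentBouts <- function(fixes, min_days = filterParams()$bout_min_days,
                         max_gap_h = filterParams()$bout_max_gap_h) {
  bouts <- list()
  for (dep in unique(fixes$deployment_id)) {
    tr <- fixes[fixes$deployment_id == dep, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    gaps <- diff(as.numeric(tr$timestamp)) > max_gap_h * 3600
    seg <- cumsum(c(0, gaps))
    for (s in unique(seg)) {
      b <- tr[seg == s, , drop = FALSE]
      span <- diff(range(as.numeric(b$timestamp))) / 86400
      if (span >= min_days) {
        b$bout_id <- sprintf("%s_b%d", dep, s + 1)
        bouts[[length(bouts) + 1]] <- b
      }
    }
  }
  bouts
}

#' Residence-in-space-and-time behavioural classification
#'
#' For each fix, residence time is the time and residence distance the
#' path length spent inside the circle of the given radius centered on the
#' fix, following the track forward and backward from the fix to the
#' (interpolated) points where the path first leaves the circle. Both are
#' normalized to [0, 1] by their bout maxima; the residual (normalized time minus
#' normalized distance) classifies the fix: negative = distance-intensive
#' (transit), otherwise time-intensive or time-and-distance-intensive
#' (sedentary, pooled).
#'
#' @param bout a single-bout data.frame with projected `x`, `y`,
#'   `timestamp`.
#' @param radius_m circle radius (m); default 30 km.
#' @param tol residuals within `tol` of zero belong to the pooled
#'   time-and-distance-intensive class and count as sedentary; only
#'   residuals below `-tol` are transit.
#' @return the bout with columns `rst_residual` and `state`
#'   (`"sedentary"`/`"transit"`).
#' @export
rstClassify <- function(bout, radius_m = filterParams()$rst_radius_m,
                        tol = 0.01) {
  if (radius_m <= 0) stop("radius must be positive", call. = FALSE)
  n <- nrow(bout)
  tt <- as.numeric(bout$timestamp)
  x <- bout$x; y <- bout$y
  # fraction of segment from inside point p1 to outside point p2 that lies
  # within radius R of center c (circle exit by quadratic interpolation)
  exit_frac <- function(p1, p2, cx, cy, R) {
    ax <- p1[1] - cx; ay <- p1[2] - cy
    bx <- p2[1] - p1[1]; by <- p2[2] - p1[2]
    bb <- bx^2 + by^2
    if (bb == 0) return(1)
    ab <- ax * bx + ay * by
    disc <- ab^2 - bb * (ax^2 + ay^2 - R^2)
    if (disc < 0) return(1)
    t <- (-ab + sqrt(disc)) / bb
    min(max(t, 0), 1)
  }
  Tres <- numeric(n); Dres <- numeric(n)
  for (i in seq_len(n)) {
    ti <- 0; di <- 0
    # forward
    j <- i
    while (j < n) {
      d2 <- (x[j + 1] - x[i])^2 + (y[j + 1] - y[i])^2
      seg_d <- sqrt((x[j + 1] - x[j])^2 + (y[j + 1] - y[j])^2)
      seg_t <- tt[j + 1] - tt[j]
      if (d2 <= radius_m^2) { ti <- ti + seg_t; di <- di + seg_d; j <- j + 1 }
      else {
        f <- exit_frac(c(x[j], y[j]), c(x[j + 1], y[j + 1]),
                       x[i], y[i], radius_m)
        ti <- ti + f * seg_t; di <- di + f * seg_d
        break
      }
    }
    # backward
    j <- i
    while (j > 1) {
      d2 <- (x[j - 1] - x[i])^2 + (y[j - 1] - y[i])^2
      seg_d <- sqrt((x[j - 1] - x[j])^2 + (y[j - 1] - y[j])^2)
      seg_t <- tt[j] - tt[j - 1]
      if (d2 <= radius_m^2) { ti <- ti + seg_t; di <- di + seg_d; j <- j - 1 }
      else {
        f <- exit_frac(c(x[j], y[j]), c(x[j - 1], y[j - 1]),
                       x[i], y[i], radius_m)
        ti <- ti + f * seg_t; di <- di + f * seg_d
        break
      }
    }
    Tres[i] <- ti; Dres[i] <- di
  }
  # residence quantities are non-negative; scaling by the bout maximum
  # maps both to [0,1] without collapsing the transit end of the range
  # (transit fixes are minimal in both time and distance, so subtracting
  # the minimum would erase the very contrast the residual encodes)
  norm01 <- function(v) {
    mx <- max(v)
    if (mx <= 0) return(rep(0, length(v)))
    v / mx
  }
  res <- norm01(Tres) - norm01(Dres)
  bout$rst_residual <- res
  bout$state <- ifelse(res < -tol, "transit", "sedentary")
  bout
}

#' Retain sedentary fixes across bouts
#'
#' Applies [segmentBouts()] then [rstClassify()] per bout and keeps
#' sedentary fixes; fixes outside any qualifying bout are removed with
#' reason `"no_bout"`, transit fixes with reason `"transit"`.
#'
#' @param fixes winter daytime fixes.
#' @param params [filterParams()].
#' @export
behavioralStateFilter <- function(fixes, params = filterParams()) {
  bouts <- segmentBouts(fixes, params$bout_min_days, params$bout_max_gap_h)
  if (length(bouts) == 0) {
    out <- fixes[0, , drop = FALSE]
    return(.attachRemoved(out, fixes, "no_bout"))
  }
  classified <- do.call(rbind, lapply(bouts, rstClassify,
                                      radius_m = params$rst_radius_m))
  kept <- classified[classified$state == "sedentary", , drop = FALSE]
  transit <- classified[classified$state == "transit", , drop = FALSE]
  in_bout <- paste(fixes$deployment_id, as.numeric(fixes$timestamp)) %in%
    paste(classified$deployment_id, as.numeric(classified$timestamp))
  nobout <- fixes[!in_bout, , drop = FALSE]
  if (nrow(transit)) transit$reason <- "transit"
  if (nrow(nobout)) nobout$reason <- "no_bout"
  common <- intersect(names(transit), names(nobout))
  removed <- rbind(transit[, common, drop = FALSE],
                   nobout[, common, drop = FALSE])
  rownames(kept) <- NULL
  attr(kept, "removed") <- removed
  kept
}

#' Two-per-day temporal thinning
#'
#' Per individual and local solar day, retains one random fix before local
#' solar noon (computed per fix from longitude) and one after, at least
#' `min_sep_h` hours apart. If one half-day is empty or no pair satisfies
#' the separation, a single fix is retained.
#'
#' @param fixes winter daytime fixes.
#' @param seed integer seed.
#' @param min_sep_h minimum separation of the retained pair (hours).
#' @return retained fixes with removal log.
#' @export
thinTwoPerDay <- function(fixes, seed = 1,
                          min_sep_h = filterParams()$thin_min_sep_h) {
  withSeed(seed, {
    local_day <- as.Date(fixes$timestamp + fixes$lon / 15 * 3600, tz = "UTC")
    noon <- solarNoon(fixes$lon, local_day)
    is_morning <- fixes$timestamp < noon
    key <- paste(fixes$deployment_id, local_day)
    keep <- logical(nrow(fixes))
    for (k in unique(key)) {
      ii <- which(key == k)
      mo <- ii[is_morning[ii]]; af <- ii[!is_morning[ii]]
      pick <- NULL
      if (length(mo) && length(af)) {
        pairs <- expand.grid(m = mo, a = af)
        sep <- as.numeric(fixes$timestamp[pairs$a]) -
          as.numeric(fixes$timestamp[pairs$m])
        ok <- which(sep >= min_sep_h * 3600)
        if (length(ok)) {
          pr <- pairs[ok[sample.int(length(ok), 1)], ]
          pick <- c(pr$m, pr$a)
        }
      }
      if (is.null(pick)) {
        pool <- c(mo, af)
        pick <- pool[sample.int(length(pool), 1)]
      }
      keep[pick] <- TRUE
    }
    .attachRemoved(fixes[keep, , drop = FALSE],
                   fixes[!keep, , drop = FALSE], "thinning")
  })
}

#' Random train/test split of locations
#'
#' @param fixes labeled, thinned fixes.
#' @param frac training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
trainTestSplit <- function(fixes, frac = filterParams()$train_fraction,
                           seed = 1) {
  stopifnot(frac > 0, frac < 1)
  withSeed(seed, {
    n <- nrow(fixes)
    ntr <- round(n * frac)
    idx <- sort(sample.int(n, ntr))
    list(train = fixes[idx, , drop = FALSE],
         test = fixes[setdiff(seq_len(n), idx), , drop = FALSE])
  })
}
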