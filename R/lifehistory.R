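# Life-history classification: kernel-density home ranges (ad hoc
# reference bandwidth scaled by a proportion), age classes on a biological
# year starting in April, and the rule cascade assigning each individual to
# one of the five observed groups while removing territory-associated
# winter locations.

#' Kernel density home range
#'
#' Bivariate normal-kernel density with per-axis bandwidth equal to
#' `smoothing_prop` times the ad hoc (reference) bandwidth
#' `sigma * n^(-1/6)`; the home range is the smallest-density region
#' containing `level` of the total density mass.
#'
#' @param x,y projected point coordinates (m).
#' @param level isopleth mass level (default 0.95).
#' @param smoothing_prop multiplier on the reference bandwidth.
#' @param grid_n evaluation grid size per axis.
#' @return An object of class `home_range`: density grid (`gx`, `gy`, `z`),
#'   density threshold `thr`, `area_km2`, mass centroid, bandwidths and
#'   sample size.
#' @export
kdeHomeRange <- function(x, y, level = 0.95, smoothing_prop = 0.7,
                         grid_n = 200) {
  n <- length(x)
  if (n < 5)
    stop("inadequate data: at least 5 points required for a home range",
         call. = FALSE)
  href <- c(sd(x), sd(y)) * n^(-1 / 6)
  h <- pmax(smoothing_prop * href, 1e-6)
  pad <- 4 * max(h)
  kd <- MASS::kde2d(x, y, h = 4 * h, n = grid_n,
                    lims = c(range(x) + c(-pad, pad),
                             range(y) + c(-pad, pad)))
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  mass <- kd$z * dx * dy
  mass <- mass / sum(mass)
  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  thr <- kd$z[ord][which(cum >= level)[1]]
  inside <- kd$z >= thr
  w <- mass * inside
  cx <- sum(outer(kd$x, rep(1, grid_n)) * w) / sum(w)
  cy <- sum(outer(rep(1, grid_n), kd$y) * w) / sum(w)
  structure(list(gx = kd$x, gy = kd$y, z = kd$z, thr = thr,
                 area_km2 = sum(inside) * dx * dy / 1e6,
                 centroid = c(x = cx, y = cy),
                 bandwidth = h, n = n, level = level),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range: %.0f%% isopleth, area %.1f km2, n = %d\n",
              100 * x$level, x$area_km2, x$n))
  invisible(x)
}

#' Point-in-home-range test
#'
#' A point is inside when the bilinearly interpolated kernel density at its
#' location is at least the isopleth threshold.
#'
#' @param hr a [kdeHomeRange()] object.
#' @param px,py projected point coordinates (m).
#' @export
insideHomeRange <- function(hr, px, py) {
  .bilinear(hr$gx, hr$gy, hr$z, px, py) >= hr$thr
}

.bilinear <- function(gx, gy, z, px, py) {
  nx <- length(gx); ny <- length(gy)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  fx <- (px - gx[1]) / dx; fy <- (py - gy[1]) / dy
  i <- floor(fx); j <- floor(fy)
  out <- numeric(length(px))
  ok <- i >= 0 & i <= nx - 2 & j >= 0 & j <= ny - 2
  if (any(ok)) {
    i1 <- i[ok] + 1L; j1 <- j[ok] + 1L
    tx <- fx[ok] - i[ok]; ty <- fy[ok] - j[ok]
    out[ok] <- z[cbind(i1, j1)] * (1 - tx) * (1 - ty) +
      z[cbind(i1 + 1L, j1)] * tx * (1 - ty) +
      z[cbind(i1, j1 + 1L)] * (1 - tx) * ty +
      z[cbind(i1 + 1L, j1 + 1L)] * tx * ty
  }
  out
}

#' Home-range isopleth polygon(s)
#'
#' Contour rings of the isopleth threshold, for export and cross-checks.
#' @param hr a [kdeHomeRange()] object.
#' @return list of two-column matrices (rings, m).
#' @export
homeRangePolygon <- function(hr) {
  cl <- grDevices::contourLines(hr$gx, hr$gy, hr$z, levels = hr$thr)
  lapply(cl, function(c1) cbind(x = c1$x, y = c1$y))
}

#' Do two home ranges overlap?
#'
#' Nonempty intersection of the isopleth regions, tested on the grid cells
#' of the first range that lie inside it.
#' @param hr1,hr2 [kdeHomeRange()] objects.
#' @export
homeRangesOverlap <- function(hr1, hr2) {
  inside1 <- which(hr1$z >= hr1$thr, arr.ind = TRUE)
  if (!nrow(inside1)) return(FALSE)
  px <- hr1$gx[inside1[, 1]]; py <- hr1$gy[inside1[, 2]]
  any(insideHomeRange(hr2, px, py))
}

#' Age class on a biological year starting in April
#'
#' @param tag_date tagging date (`Date`).
#' @param age_at_tagging age in biological years at tagging.
#' @param date date at which to evaluate the age.
#' @return list with `age` (biological years) and `age_class`
#'   (`"adult"` for 4 or older, `"non-adult"` otherwise).
#' @export
assignAgeClass <- function(tag_date, age_at_tagging, date) {
  if (is.na(tag_date) || is.na(age_at_tagging))
    stop("missing age metadata (tag date or age at tagging)", call. = FALSE)
  bioYear <- function(d) {
    d <- as.Date(d)
    as.integer(format(d, "%Y")) - (as.integer(format(d, "%m")) < 4)
  }
  age <- age_at_tagging + bioYear(date) - bioYear(tag_date)
  list(age = age, age_class = if (age >= 4) "adult" else "non-adult")
}

# distance (m) from points to a polygon ring; 0 inside.
.distToPolygon <- function(px, py, ring) {
  inside <- pointInPolygon(px, py, ring)
  d <- rep(0, length(px))
  out <- which(!inside)
  if (length(out)) {
    xs <- ring[, 1]; ys <- ring[, 2]
    n <- nrow(ring)
    x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
    for (i in out) {
      ex <- x2 - xs; ey <- y2 - ys
      t <- pmin(1, pmax(0, ((px[i] - xs) * ex + (py[i] - ys) * ey) /
                          pmax(ex^2 + ey^2, 1e-12)))
      dd <- (px[i] - (xs + t * ex))^2 + (py[i] - (ys + t * ey))^2
      d[i] <- sqrt(min(dd))
    }
  }
  d
}

#' Classify one individual and filter its winter locations
#'
#' Applies the life-history rule cascade: (1) migrants (origin or summer
#' range north of 58.25 N) keep all study-area winter fixes; (2)
#' nestling-tagged birds lose fixes within one year of tagging and within
#' 3.2 km of the natal site, while unknown-natal first-year birds with
#' overlapping small (< 200 km2) seasonal ranges are removed entirely; (3)
#' 2-3 year olds not tagged as nestlings keep all winter fixes; (4) adults
#' whose summer fixes all lie more than 16 km outside the study area keep
#' all winter fixes (non-territorial), those with near-boundary summer
#' ranges lose fixes inside the summer range, and those with inadequate
#' summer data (< 25 locations or < 30 days) are removed; (5) remaining
#' adults are territory holders when the summer 95% KDE is under 200 km2
#' (winter fixes inside the governing summer KDE removed) and floaters
#' otherwise.
#'
#' @param meta one-row deployment metadata (tag_date, age_at_tagging,
#'   tagged_as_nestling, natal_lon/lat, tag_lat).
#' @param winter_fixes,summer_fixes seasonal fix sets of the individual
#'   (projected `x`, `y` plus `lon`, `lat`, `timestamp`).
#' @param study_area study-area ring (matrix, m).
#' @param proj the [laeaProjection()] used.
#' @param reference_date date at which age class is evaluated (default:
#'   first winter fix).
#' @return list with `label`, `age_class`, `migratory_status`,
#'   `territory_status`, `fixes` (retained winter fixes), `removed`
#'   (removed winter fixes with reasons) and `removed_individual`
#'   (`NA` or a reason string when the whole individual is dropped).
#' @export
classifyAndFilter <- function(meta, winter_fixes, summer_fixes, study_area,
                              proj = laeaProjection(),
                              reference_date = NULL) {
  if (isTRUE(meta$tagged_as_nestling) && meta$age_at_tagging >= 4)
    stop("contradictory metadata: tagged as nestling but adult-aged",
         call. = FALSE)
  if (is.null(reference_date)) {
    reference_date <- if (nrow(winter_fixes))
      as.Date(min(winter_fixes$timestamp), tz = "UTC") else meta$tag_date
  }
  age <- assignAgeClass(meta$tag_date, meta$age_at_tagging, reference_date)

  out <- function(label, age_class, mig, terr, fixes, removed,
                  removed_individual = NA_character_) {
    list(label = label, age_class = age_class, migratory_status = mig,
         territory_status = terr, fixes = fixes, removed = removed,
         removed_individual = removed_individual)
  }
  removed <- winter_fixes[0, , drop = FALSE]
  removed$reason <- character(0)
  drop_rows <- function(fixes, idx, reason) {
    if (!length(idx)) return(list(fixes = fixes, removed = removed))
    r <- fixes[idx, , drop = FALSE]
    r$reason <- reason
    list(fixes = fixes[-idx, , drop = FALSE], removed = rbind(removed, r))
  }

  # winter fixes outside the study area are never modeled
  in_sa <- pointInPolygon(winter_fixes$x, winter_fixes$y, study_area)
  st <- drop_rows(winter_fixes, which(!in_sa), "outside_study_area")
  wf <- st$fixes; removed <- st$removed

  summer_hr <- NULL
  summer_adequate <- FALSE
  if (nrow(summer_fixes) >= 5) {
    span <- diff(range(as.numeric(summer_fixes$timestamp))) / 86400
    summer_adequate <- nrow(summer_fixes) >= 25 && span >= 30
    summer_hr <- kdeHomeRange(summer_fixes$x, summer_fixes$y)
  }

  # rule 1: migratory status from origin or summer-range latitude
  summer_lat <- if (!is.null(summer_hr)) {
    unprojectXY(proj, summer_hr$centroid[1], summer_hr$centroid[2])$lat
  } else if (nrow(summer_fixes)) mean(summer_fixes$lat) else NA_real_
  migrant <- (!is.na(meta$tag_lat) && meta$tag_lat > 58.25) ||
    (!is.na(summer_lat) && summer_lat > 58.25)
  if (migrant) {
    lbl <- if (age$age_class == "adult") "Adult Migrant" else
      "Non-adult Migrant"
    return(out(lbl, age$age_class, "migrant", "non-territorial",
               wf, removed))
  }

  # rule 2a: known natal site (nestling-tagged)
  if (isTRUE(meta$tagged_as_nestling) && is.finite(meta$natal_lon)) {
    natal <- projectLonLat(proj, meta$natal_lon, meta$natal_lat)
    within_year <- as.Date(wf$timestamp, tz = "UTC") <= meta$tag_date + 365
    d <- sqrt((wf$x - natal$x)^2 + (wf$y - natal$y)^2)
    st <- drop_rows(wf, which(within_year & d <= 3200), "natal_core")
    wf <- st$fixes; removed <- st$removed
    if (age$age_class == "non-adult")
      return(out("Non-adult Non-migrant", "non-adult", "non-migrant",
                 "non-territorial", wf, removed))
  }

  # rule 2b: first-calendar-year, natal site unknown
  if (age$age <= 1 && !isTRUE(meta$tagged_as_nestling) ||
      (age$age <= 1 && isTRUE(meta$tagged_as_nestling) &&
         !is.finite(meta$natal_lon))) {
    if (nrow(wf) >= 5 && !is.null(summer_hr)) {
      winter_hr <- kdeHomeRange(wf$x, wf$y)
      if (homeRangesOverlap(summer_hr, winter_hr) &&
          summer_hr$area_km2 < 200 && winter_hr$area_km2 < 200) {
        r <- wf; if (nrow(r)) r$reason <- "possible_natal_territory"
        return(out(NA_character_, "non-adult", "non-migrant", NA_character_,
                   wf[0, , drop = FALSE], rbind(removed, r),
                   "possible_natal_territory"))
      }
    }
    return(out("Non-adult Non-migrant", "non-adult", "non-migrant",
               "non-territorial", wf, removed))
  }

  # rule 3: 2-3 year olds not tagged as nestlings
  if (age$age_class == "non-adult")
    return(out("Non-adult Non-migrant", "non-adult", "non-migrant",
               "non-territorial", wf, removed))

  # rules 4-5: adults (non-migrant)
  dist_sa <- if (nrow(summer_fixes))
    .distToPolygon(summer_fixes$x, summer_fixes$y, study_area) else numeric(0)
  if (!length(dist_sa) || all(dist_sa > 16000))
    return(out("Adult Non-migrant Non-territorial", "adult", "non-migrant",
               "non-territorial", wf, removed))
  if (!summer_adequate) {
    r <- wf; if (nrow(r)) r$reason <- "inadequate_summer_data"
    return(out(NA_character_, "adult", "non-migrant", NA_character_,
               wf[0, , drop = FALSE], rbind(removed, r),
               "inadequate_summer_data"))
  }
  centroid_inside <- pointInPolygon(summer_hr$centroid[1],
                                    summer_hr$centroid[2], study_area)
  if (!centroid_inside) {
    st <- drop_rows(wf, which(insideHomeRange(summer_hr, wf$x, wf$y)),
                    "inside_summer_range")
    return(out("Adult Non-migrant Non-territorial", "adult", "non-migrant",
               "non-territorial", st$fixes, st$removed))
  }
  if (summer_hr$area_km2 < 200) {
    st <- drop_rows(wf, which(insideHomeRange(summer_hr, wf$x, wf$y)),
                    "inside_summer_range")
    return(out("Adult Non-migrant Territory-holder", "adult", "non-migrant",
               "territory holder", st$fixes, st$removed))
  }
  out("Adult Non-migrant Non-territorial", "adult", "non-migrant",
      "non-territorial", wf, removed)
}

#' Classify all deployments
#'
#' Runs [classifyAndFilter()] over a deployment table, returning the
#' retained winter fixes annotated with `life_history` and a per-individual
#' label table.
#'
#' @param winter_fixes,summer_fixes seasonal fix sets (all deployments).
#' @param deployments deployment metadata table.
#' @param study_area study-area ring.
#' @param proj the [laeaProjection()] used.
#' @return list with `fixes`, `labels` (one row per deployment) and
#'   `removed`.
#' @export
classifyDeployments <- function(winter_fixes, summer_fixes, deployments,
                                study_area, proj = laeaProjection()) {
  fixes <- list(); labels <- list(); removed <- list()
  for (i in seq_len(nrow(deployments))) {
    meta <- deployments[i, , drop = FALSE]
    dep <- meta$deployment_id
    wf <- winter_fixes[winter_fixes$deployment_id == dep, , drop = FALSE]
    sf <- summer_fixes[summer_fixes$deployment_id == dep, , drop = FALSE]
    res <- classifyAndFilter(meta, wf, sf, study_area, proj)
    labels[[dep]] <- data.frame(
      deployment_id = dep, label = res$label,
      age_class = res$age_class, migratory_status = res$migratory_status,
      territory_status = res$territory_status,
      removed_individual = res$removed_individual,
      n_retained = nrow(res$fixes), stringsAsFactors = FALSE)
    if (nrow(res$fixes)) {
      res$fixes$life_history <- res$label
      fixes[[dep]] <- res$fixes
    }
    if (nrow(res$removed)) removed[[dep]] <- res$removed
  }
  list(fixes = do.call(rbind, fixes),
       labels = do.call(rbind, labels),
       removed = do.call(rbind, removed))
}
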