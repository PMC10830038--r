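# Minimal planar polygon utilities (projected coordinates, meters).
# Polygons are matrices with columns x, y; rings need not be closed
# explicitly (the last->first edge is implied). Multi-part polygons are
# lists of such rings (holes are not used anywhere in the pipeline).

#' Planar polygon area
#'
#' Shoelace formula; absolute value, so ring orientation is irrelevant.
#' @param ring two-column matrix of vertex coordinates (m).
#' @return Area in km^2.
#' @export
polygonArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2 / 1e6
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule with a horizontal ray; boundary points may fall on either
#' side and are not treated specially.
#' @param px,py point coordinates (m).
#' @param ring two-column vertex matrix, or a list of rings (a point is
#'   inside if it is inside an odd number of rings).
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, ring) {
  if (is.list(ring) && !is.matrix(ring)) {
    inside <- rep(0L, length(px))
    for (r in ring) inside <- inside + pointInPolygon(px, py, r)
    return(inside %% 2L == 1L)
  }
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  jx <- c(x[n], x[-n]); jy <- c(y[n], y[-n])
  out <- logical(length(px))
  for (k in seq_len(n)) {
    x1 <- jx[k]; y1 <- jy[k]; x2 <- x[k]; y2 <- y[k]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      out <- xor(out, crosses & (px < xint))
    }
  }
  out
}

#' Rectangle polygon from an extent
#'
#' @param ext numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
rectPolygon <- function(ext) {
  cbind(x = c(ext[1], ext[2], ext[2], ext[1]),
        y = c(ext[3], ext[3], ext[4], ext[4]))
}

#' Euclidean distance between point sets
#'
#' @param ax,ay,bx,by coordinates (m).
#' @return For `nearestDistance`, per-a-point distance (m) to the nearest
#'   b point.
#' @export
nearestDistance <- function(ax, ay, bx, by) {
  vapply(seq_along(ax), function(i) {
    sqrt(min((bx - ax[i])^2 + (by - ay[i])^2))
  }, numeric(1))
}

# ---- GeoJSON I/O -----------------------------------------------------------

#' Read/write polygons as GeoJSON
#'
#' Polygons are stored as a named list of rings (two-column matrices) in
#' projected meters. On write, coordinates are inverse-projected to lon/lat
#' (GeoJSON's native CRS); on read they are projected back, so geographic
#' inputs are reprojected on load.
#'
#' @param polys named list of rings (matrices with x, y in m).
#' @param path file path.
#' @param proj a [laeaProjection()].
#' @export
writePolygonsGeoJSON <- function(polys, path, proj) {
  feats <- lapply(names(polys), function(nm) {
    ring <- polys[[nm]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close ring
    ll <- unprojectXY(proj, ring[, 1], ring[, 2])
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(as.matrix(ll)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname writePolygonsGeoJSON
#' @export
readPolygonsGeoJSON <- function(path, proj) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a FeatureCollection", call. = FALSE)
  polys <- list()
  for (f in gj$features) {
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("poly", length(polys) + 1)
    co <- f$geometry$coordinates[[1]]
    ll <- do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
    xy <- projectLonLat(proj, ll[, 1], ll[, 2])
    ring <- cbind(x = xy$x, y = xy$y)
    # drop duplicated closing vertex
    n <- nrow(ring)
    if (n > 1 && isTRUE(all.equal(ring[1, ], ring[n, ], tolerance = 1e-9,
                                  check.attributes = FALSE)))
      ring <- ring[-n, , drop = FALSE]
    polys[[nm]] <- ring
  }
  polys
}
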