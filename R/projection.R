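# Lambert azimuthal equal-area projection on a spherical earth.
# All package distances and areas are computed in this projected plane;
# longitude/latitude are retained only for solar geometry and the
# 58.25 degree N latitude rule.

.EARTH_R <- 6371007.181  # authalic radius, m

#' Equal-area projection descriptor
#'
#' Creates a Lambert azimuthal equal-area (LAEA, spherical) projection
#' centered on the study area. Used project-wide so that distances (m) and
#' areas (km^2) can be computed with plane geometry.
#'
#' @param lon0,lat0 projection center (decimal degrees).
#' @return An object of class `laea_projection`.
#' @export
laeaProjection <- function(lon0 = -107.5, lat0 = 43) {
  structure(list(lon0 = lon0, lat0 = lat0, R = .EARTH_R),
            class = "laea_projection")
}

#' @export
print.laea_projection <- function(x, ...) {
  cat(sprintf("LAEA (spherical) centered at lon %g, lat %g\n", x$lon0, x$lat0))
  invisible(x)
}

#' Forward/inverse Lambert azimuthal equal-area projection
#'
#' `projectLonLat` maps lon/lat (degrees) to projected x/y (m);
#' `unprojectXY` inverts it.
#'
#' @param proj a [laeaProjection()] object.
#' @param lon,lat coordinates in decimal degrees.
#' @param x,y projected coordinates in meters.
#' @return data.frame with `x`,`y` (or `lon`,`lat`).
#' @export
projectLonLat <- function(proj, lon, lat) {
  stopifnot(inherits(proj, "laea_projection"))
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE))
    stop("lon/lat out of bounds", call. = FALSE)
  d <- pi / 180
  lam <- (lon - proj$lon0) * d
  phi <- lat * d
  phi0 <- proj$lat0 * d
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  k <- sqrt(2 / denom)
  data.frame(x = proj$R * k * cos(phi) * sin(lam),
             y = proj$R * k * (cos(phi0) * sin(phi) -
                                 sin(phi0) * cos(phi) * cos(lam)))
}

#' @rdname projectLonLat
#' @export
unprojectXY <- function(proj, x, y) {
  stopifnot(inherits(proj, "laea_projection"))
  d <- pi / 180
  phi0 <- proj$lat0 * d
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * proj$R)))
  phi <- ifelse(rho < 1e-9, phi0,
                asin(cos(c_ang) * sin(phi0) +
                       y * sin(c_ang) * cos(phi0) / pmax(rho, 1e-9)))
  lam <- ifelse(rho < 1e-9, 0,
                atan2(x * sin(c_ang),
                      rho * cos(phi0) * cos(c_ang) -
                        y * sin(phi0) * sin(c_ang)))
  data.frame(lon = proj$lon0 + lam / d, lat = phi / d)
}
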