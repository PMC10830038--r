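# NOAA solar calculations: equation of time, solar declination, sunrise and
# sunset (zenith 90.833 degrees), and local solar noon. The Fourier-series
# forms below are the ones used in the NOAA solar calculator; accuracy is
# well under a minute at mid latitudes, which is ample for a +/- 1 h
# daytime margin.

.fractionalYear <- function(time) {
  # radians; time is POSIXct UTC
  lt <- as.POSIXlt(time, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  2 * pi / 365 * (lt$yday + (hour - 12) / 24)
}

#' Equation of time and solar declination
#'
#' @param time POSIXct (UTC).
#' @return `solarParams` returns a data.frame with `eqtime` (minutes) and
#'   `decl` (radians).
#' @export
solarParams <- function(time) {
  g <- .fractionalYear(time)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  data.frame(eqtime = eqtime, decl = decl)
}

#' Sunrise, sunset and solar noon (UTC)
#'
#' NOAA solar-position method with the standard refraction-corrected zenith
#' of 90.833 degrees for sunrise/sunset. Where the sun never rises (or never
#' sets) on the date at that latitude, `sunrise`/`sunset` are `NA` and
#' `polar` is `"night"` (or `"day"`).
#'
#' @param lat,lon location in decimal degrees (lon positive east).
#' @param date a `Date`, or POSIXct whose UTC date is used.
#' @return data.frame with POSIXct columns `sunrise`, `sunset`,
#'   `solar_noon` and character `polar` (`"none"`, `"day"`, `"night"`).
#' @export
sunriseSunset <- function(lat, lon, date) {
  if (inherits(date, "POSIXct")) date <- as.Date(date, tz = "UTC")
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); date <- rep_len(date, n)
  noonGuess <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
  sp <- solarParams(noonGuess)
  zen <- 90.833 * pi / 180
  phi <- lat * pi / 180
  cosha <- cos(zen) / (cos(phi) * cos(sp$decl)) - tan(phi) * tan(sp$decl)
  polar <- ifelse(cosha > 1, "night", ifelse(cosha < -1, "day", "none"))
  ha <- acos(pmin(1, pmax(-1, cosha))) * 180 / pi  # degrees
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- day0 + 60 * (720 - 4 * (lon + ha) - sp$eqtime)
  sunset  <- day0 + 60 * (720 - 4 * (lon - ha) - sp$eqtime)
  noon    <- day0 + 60 * (720 - 4 * lon - sp$eqtime)
  sunrise[polar != "none"] <- NA
  sunset[polar != "none"] <- NA
  data.frame(sunrise = sunrise, sunset = sunset, solar_noon = noon,
             polar = polar)
}

#' Local solar noon (UTC instant)
#'
#' @inheritParams sunriseSunset
#' @return POSIXct vector of solar-noon instants.
#' @export
solarNoon <- function(lon, date) {
  sunriseSunset(0, lon, date)$solar_noon
}
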