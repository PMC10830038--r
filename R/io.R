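# Telemetry CSV and raster-stack I/O, plus the bundled worked-example
# tables. Telemetry CSV schema: deployment_id, timestamp (ISO-8601 UTC),
# lon, lat, fix_type (GPS|Argos), argos_class (3|2|1|other|empty).

#' Read telemetry fixes from CSV
#'
#' Malformed rows (unparseable timestamp, out-of-bounds coordinates,
#' unknown fix source) are collected into the `rejected` attribute with a
#' reason, not silently dropped. Projected coordinates are added from
#' `proj`.
#'
#' @param path CSV path.
#' @param proj a [laeaProjection()].
#' @return data.frame of fixes with projected `x`, `y`; rejected rows in
#'   the `rejected` attribute.
#' @export
readTelemetry <- function(path, proj = laeaProjection()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("argos_class" %in% names(df))
    df$argos_class <- as.character(df$argos_class)
  need <- c("deployment_id", "timestamp", "lon", "lat", "fix_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("telemetry file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"argos_class" %in% names(df)) df$argos_class <- NA_character_
  df$argos_class[!is.na(df$argos_class) & df$argos_class == ""] <-
    NA_character_
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(strptime(df$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                 tz = "UTC"))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(ts)] <- "bad_timestamp"
  bad_lat <- !is.finite(df$lat) | abs(df$lat) > 90
  bad_lon <- !is.finite(df$lon) | abs(df$lon) > 180
  reason[is.na(reason) & (bad_lat | bad_lon)] <- "coordinate_bounds"
  reason[is.na(reason) & !df$fix_type %in% c("GPS", "Argos")] <-
    "unknown_source"
  ok <- is.na(reason)
  out <- df[ok, , drop = FALSE]
  out$timestamp <- ts[ok]
  if (nrow(out)) {
    xy <- projectLonLat(proj, out$lon, out$lat)
    out$x <- xy$x; out$y <- xy$y
  } else { out$x <- numeric(0); out$y <- numeric(0) }
  rej <- df[!ok, , drop = FALSE]
  rej$reason <- reason[!ok]
  rownames(out) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Write telemetry fixes to CSV
#'
#' @param fixes telemetry data.frame.
#' @param path output path.
#' @export
writeTelemetry <- function(fixes, path) {
  out <- data.frame(
    deployment_id = fixes$deployment_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = sprintf("%.10g", fixes$lon), lat = sprintf("%.10g", fixes$lat),
    fix_type = fixes$fix_type,
    argos_class = ifelse(is.na(fixes$argos_class), "", fixes$argos_class))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a covariate stack as ASCII grids plus a JSON sidecar
#'
#' Each layer is one ESRI ASCII grid next to a `<name>.json` metadata
#' sidecar mapping files to base variable, category, extent and statistic.
#'
#' @param stack a [CovariateStack-class].
#' @param dir directory.
#' @param name stack name (file prefix).
#' @export
writeStack <- function(stack, dir, name = "stack") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- stack@meta
  meta$file <- sprintf("%s_%02d.asc", name, seq_len(nrow(meta)))
  for (i in seq_len(nrow(meta)))
    writeAsc(stack@layers[[i]], file.path(dir, meta$file[i]))
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeStack
#' @export
readStack <- function(dir, name = "stack", crs = "laea") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow(meta)), function(i)
    readAsc(file.path(dir, meta$file[i]), crs = crs))
  names(layers) <- meta$name
  covariateStack(layers, meta[, setdiff(names(meta), "file")])
}

#' Bundled worked-example tables
#'
#' `lifeHistoryAAFTable()` returns the bundled per-life-history-group
#' area-adjusted-frequency bin table of a published winter golden-eagle
#' distribution model (10 equal-interval intensity bins, AAF per group);
#' `surfaceManagementTable()` the matching surface-management percentage
#' table (study-area share and top-20%/top-10% habitat shares per
#' management entity). Both serve as worked examples for the evaluation
#' and comparison arithmetic.
#'
#' @return data.frame.
#' @export
lifeHistoryAAFTable <- function() {
  read.csv(system.file("extdata", "life_history_aaf.csv",
                       package = "raptorwinter"),
           check.names = FALSE)
}

#' @rdname lifeHistoryAAFTable
#' @export
surfaceManagementTable <- function() {
  read.csv(system.file("extdata", "surface_management.csv",
                       package = "raptorwinter"),
           check.names = FALSE)
}
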