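# Raster container helpers: constructors, accessors, extraction, text I/O.
# Grid convention: cell-centered, north-up; matrix row 1 = northernmost row.

#' Create a GridRaster
#'
#' @param values numeric matrix (row 1 = northern edge).
#' @param xll,yll lower-left corner coordinates (m).
#' @param res cell size (m).
#' @param crs CRS descriptor string.
#' @return A [GridRaster-class].
#' @export
gridRaster <- function(values, xll = 0, yll = 0, res = 120, crs = "laea") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GridRaster", values = values, xll = xll, yll = yll,
      res = res, crs = crs)
}

#' Raster accessors
#'
#' `rasterValues` returns the value matrix, `rasterRes` the cell size,
#' `cellArea` the cell area in km^2, and `rasterExtent` the
#' `c(xmin, xmax, ymin, ymax)` extent.
#' @param x a [GridRaster-class].
#' @export
rasterValues <- function(x) x@values

#' @rdname rasterValues
#' @export
rasterRes <- function(x) x@res

#' @rdname rasterValues
#' @export
cellArea <- function(x) (x@res / 1000)^2

#' @rdname rasterValues
#' @export
rasterExtent <- function(x) {
  v <- x@values
  c(xmin = x@xll, xmax = x@xll + ncol(v) * x@res,
    ymin = x@yll, ymax = x@yll + nrow(v) * x@res)
}

#' Cell center coordinates
#'
#' @param x a [GridRaster-class].
#' @return data.frame with `x`, `y`, `row`, `col`, `value` for every cell,
#'   in column-major cell order.
#' @export
cellCenters <- function(x) {
  v <- x@values
  nr <- nrow(v); nc <- ncol(v)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(
    x = x@xll + (col - 0.5) * x@res,
    y = x@yll + (nr - row + 0.5) * x@res,
    row = row, col = col, value = as.vector(v))
}

#' Map point coordinates to raster row/col indices
#'
#' Points outside the extent get NA indices.
#' @param x a [GridRaster-class].
#' @param px,py point coordinates (m).
#' @export
cellIndex <- function(x, px, py) {
  v <- x@values
  col <- floor((px - x@xll) / x@res) + 1L
  rowfromS <- floor((py - x@yll) / x@res) + 1L   # 1 = southern row
  row <- nrow(v) - rowfromS + 1L
  bad <- col < 1L | col > ncol(v) | row < 1L | row > nrow(v)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' Nearest-cell extraction; NA outside the extent.
#' @inheritParams cellIndex
#' @export
extractValues <- function(x, px, py) {
  idx <- cellIndex(x, px, py)
  out <- rep(NA_real_, length(px))
  ok <- !is.na(idx$row)
  out[ok] <- x@values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Assert that two rasters share grid geometry
#'
#' @param a,b [GridRaster-class] objects.
#' @export
assertAligned <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)) ||
      !isTRUE(all.equal(c(a@xll, a@yll, a@res), c(b@xll, b@yll, b@res))))
    stop("rasters are not aligned: differing origin, resolution or dimensions",
         call. = FALSE)
  invisible(TRUE)
}

#' Stack accessors
#'
#' `stackLayers` returns the layer list, `stackMeta` the metadata table,
#' `getLayer` one layer by name, and `nLayers` the layer count.
#' @param x a [CovariateStack-class].
#' @param name layer name.
#' @export
stackLayers <- function(x) x@layers

#' @rdname stackLayers
#' @export
stackMeta <- function(x) x@meta

#' @rdname stackLayers
#' @export
getLayer <- function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'",
                                       call. = FALSE)
  x@layers[[name]]
}

#' @rdname stackLayers
#' @export
nLayers <- function(x) length(x@layers)

#' Build a CovariateStack from layers and metadata
#'
#' @param layers named list of [GridRaster-class].
#' @param meta metadata data.frame; defaults are filled for missing columns.
#' @export
covariateStack <- function(layers, meta = NULL) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list", call. = FALSE)
  if (is.null(meta))
    meta <- data.frame(name = names(layers))
  if (!"base" %in% names(meta)) meta$base <- meta$name
  if (!"category" %in% names(meta)) meta$category <- "uncategorized"
  if (!"extent_m" %in% names(meta))
    meta$extent_m <- layers[[1]]@res
  if (!"statistic" %in% names(meta)) meta$statistic <- "none"
  if (!"categorical" %in% names(meta)) meta$categorical <- FALSE
  rownames(meta) <- NULL
  new("CovariateStack", layers = layers, meta = meta)
}

#' Subset a stack by layer names
#'
#' @param x a [CovariateStack-class].
#' @param names layer names to keep.
#' @export
subsetStack <- function(x, names) {
  keep <- match(names, x@meta$name)
  if (anyNA(keep)) stop("unknown layer(s): ",
                        paste(names[is.na(keep)], collapse = ", "),
                        call. = FALSE)
  new("CovariateStack", layers = x@layers[keep],
      meta = x@meta[keep, , drop = FALSE])
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Read/write a raster as ESRI ASCII grid
#'
#' A plain-text raster format with a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south. The CRS descriptor is not part of the format;
#' supply it on read.
#'
#' @param x a [GridRaster-class] (for writing).
#' @param path file path.
#' @param crs CRS descriptor to attach on read.
#' @export
writeAsc <- function(x, path) {
  v <- x@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x@xll),
    sprintf("yllcorner %.10g", x@yll),
    sprintf("cellsize %.10g", x@res),
    "NODATA_value -9999"), con)
  vv <- v
  vv[!is.finite(vv)] <- -9999
  writeLines(apply(vv, 1, function(r) paste(format(r, digits = 17),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname writeAsc
#' @export
readAsc <- function(path, crs = "laea") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- getv("ncols"); nr <- getv("nrows")
  nodata <- getv("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == nodata] <- NA_real_
  gridRaster(v, xll = getv("xllcorner"), yll = getv("yllcorner"),
             res = getv("cellsize"), crs = crs)
}
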