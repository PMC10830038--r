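#' @import methods
#' @import stats
#' @import utils
#' @importFrom MASS kde2d
#' @importFrom grDevices contourLines
NULL

#' GridRaster: a regular, cell-centered, equal-area raster
#'
#' A minimal single-band raster on a regular grid in a projected equal-area
#' coordinate system. Values are stored as a numeric matrix with rows running
#' north to south (row 1 is the northern edge) and columns west to east, the
#' convention of ESRI ASCII grids read top-down. `xll`/`yll` give the
#' coordinates of the lower-left corner of the grid (not a cell center);
#' `res` is the square cell size in meters.
#'
#' @slot values numeric matrix of cell values (`NA` = NoData).
#' @slot xll,yll lower-left corner of the raster extent (m).
#' @slot res cell size (m).
#' @slot crs free-text descriptor of the projected CRS.
#' @export
setClass("GridRaster",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 res = "numeric", crs = "character"),
  prototype(xll = 0, yll = 0, res = 120, crs = "laea"))

setValidity("GridRaster", function(object) {
  if (!is.numeric(object@values)) return("values must be a numeric matrix")
  if (length(object@res) != 1 || !is.finite(object@res) || object@res <= 0)
    return("res must be a single positive number")
  if (length(object@xll) != 1 || length(object@yll) != 1)
    return("xll and yll must be scalars")
  TRUE
})

#' CovariateStack: a set of aligned covariate layers with metadata
#'
#' Layers share grid geometry. The metadata table carries, per layer, the
#' base-variable name, its variable category, the focal extent (m) and the
#' focal statistic used to derive it (`"none"` for raw base layers), plus
#' whether the layer is categorical (e.g. an ecoregion layer).
#'
#' @slot layers named list of [GridRaster-class] objects.
#' @slot meta data.frame with columns `name`, `base`, `category`, `extent_m`,
#'   `statistic`, `categorical`.
#' @export
setClass("CovariateStack",
  representation(layers = "list", meta = "data.frame"))

setValidity("CovariateStack", function(object) {
  if (length(object@layers) == 0) return("stack has no layers")
  if (!all(vapply(object@layers, is, logical(1), "GridRaster")))
    return("all layers must be GridRaster objects")
  if (nrow(object@meta) != length(object@layers))
    return("meta must have one row per layer")
  need <- c("name", "base", "category", "extent_m", "statistic", "categorical")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must have columns:", paste(need, collapse = ", ")))
  g <- object@layers[[1]]
  ok <- vapply(object@layers, function(l) {
    identical(dim(l@values), dim(g@values)) &&
      isTRUE(all.equal(c(l@xll, l@yll, l@res), c(g@xll, g@yll, g@res)))
  }, logical(1))
  if (!all(ok)) return("layers are not aligned to a common grid")
  TRUE
})

#' IntensitySurface: per-cell relative intensity of use
#'
#' A [GridRaster-class] whose non-NA values are a relative intensity of use.
#' Two scalings occur in the package: probability scaling (values sum to 1;
#' the generative truth) and min-max scaling to [0, 1] (the mapped model
#' output). The `scaling` slot records which one applies.
#'
#' @slot scaling `"sum1"` or `"minmax"`.
#' @slot area label of the area definition (`"modeled"`, `"buffered"`,
#'   `"study"`).
#' @export
setClass("IntensitySurface", contains = "GridRaster",
  representation(scaling = "character", area = "character"),
  prototype(scaling = "sum1", area = "study"))

#' MaxentModel: a fitted penalized maximum-entropy intensity model
#'
#' @slot features the feature definition list built by [buildFeatures()].
#' @slot lambda named numeric vector of feature coefficients.
#' @slot reg_multiplier regularization multiplier used.
#' @slot beta_j per-feature L1 penalty scales.
#' @slot gain_credit per-feature accumulated penalized-gain credit (used for
#'   percent contribution).
#' @slot objective penalized log-likelihood trace across optimizer sweeps.
#' @slot converged logical convergence flag.
#' @slot train_range per-covariate min/max over training support (clamping).
#' @slot n_presence,n_background training sample sizes.
#' @export
setClass("MaxentModel",
  representation(features = "list", lambda = "numeric",
                 reg_multiplier = "numeric", beta_j = "numeric",
                 gain_credit = "numeric", objective = "numeric",
                 converged = "logical", train_range = "matrix",
                 n_presence = "numeric", n_background = "numeric"))

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat(sprintf("<%s> %d x %d cells, res %g m, origin (%g, %g), crs: %s\n",
              class(object), nrow(v), ncol(v), object@res,
              object@xll, object@yll, object@crs))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%.4g, %.4g], NA cells: %d\n",
                min(fin), max(fin), sum(!is.finite(v))))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("<CovariateStack> %d layers on a %d x %d grid (res %g m)\n",
              length(object@layers), nrow(object@layers[[1]]@values),
              ncol(object@layers[[1]]@values), object@layers[[1]]@res))
  print(object@meta[, c("name", "category", "extent_m", "statistic")],
        row.names = FALSE)
})

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(abs(object@lambda) > 0)
  cat(sprintf(
    "<MaxentModel> %d features (%d active), reg multiplier %g\n",
    length(object@lambda), nz, object@reg_multiplier))
  cat(sprintf("  n presence %d, n background %d, converged: %s\n",
              object@n_presence, object@n_background, object@converged))
  cat(sprintf("  penalized log-likelihood: %.6f (%d sweeps)\n",
              tail(object@objective, 1), length(object@objective)))
})
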