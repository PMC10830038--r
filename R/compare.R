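# Surface comparison and land-management summaries: rank correlation of
# two intensity surfaces, percent overlap of top-quantile areas, and
# observed:expected concentration ratios by surface-management category.

#' Spearman correlation of two surfaces
#'
#' Cell-wise Spearman rank correlation (mid-rank ties) over the mutual
#' valid-data footprint, optionally restricted to a mask.
#'
#' @param s1,s2 aligned [GridRaster-class] surfaces.
#' @param mask optional logical matrix.
#' @export
surfaceCorrelation <- function(s1, s2, mask = NULL) {
  assertAligned(s1, s2)
  v1 <- as.vector(s1@values); v2 <- as.vector(s2@values)
  ok <- is.finite(v1) & is.finite(v2)
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  cor(v1[ok], v2[ok], method = "spearman")
}

# deterministic top-q cell set by area: highest values first, ties broken
# by cell order
.topCells <- function(v, ok, q) {
  idx <- which(ok)
  n_top <- round(q * length(idx))
  ord <- idx[order(-v[idx], idx)]
  head(ord, n_top)
}

#' Percent overlap of top-quantile areas
#'
#' The top q of each surface is its highest-value cells covering a q share
#' of the mutual footprint area (ties broken by value then deterministic
#' cell order). Overlap is the percentage of the first surface's top set
#' that falls in the second's (the sets are equal-area by construction).
#'
#' @param s1,s2 aligned [GridRaster-class] surfaces.
#' @param q area quantile (e.g. 0.10 or 0.20).
#' @param mask optional logical matrix.
#' @return Percent overlap in [0, 100].
#' @export
topQuantileOverlap <- function(s1, s2, q = 0.10, mask = NULL) {
  assertAligned(s1, s2)
  v1 <- as.vector(s1@values); v2 <- as.vector(s2@values)
  ok <- is.finite(v1) & is.finite(v2)
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  t1 <- .topCells(v1, ok, q)
  t2 <- .topCells(v2, ok, q)
  if (!length(t1)) return(NA_real_)
  100 * length(intersect(t1, t2)) / length(t1)
}

#' Observed:expected high-use habitat concentration ratio
#'
#' The share of top-decile habitat in a management category divided by the
#' category's share of the study area, rounded to two decimals (the
#' convention of the summary tables this mirrors).
#'
#' @param top10_pct percentage of the top-10% habitat in the category.
#' @param area_pct percentage of the study area in the category.
#' @param digits rounding digits (default 2).
#' @export
observedExpectedRatio <- function(top10_pct, area_pct, digits = 2) {
  round(top10_pct / area_pct, digits)
}

#' Surface-management summary table
#'
#' Per management category: percentage of the study area, percentage of
#' the top 20% and top 10% habitat areas, and the observed:expected ratio
#' (top-10% share over area share).
#'
#' @param surface min-max scaled [IntensitySurface-class].
#' @param categories a [GridRaster-class] of integer category codes
#'   aligned to the surface, or a named list of polygon rings.
#' @param labels optional names for integer codes.
#' @return data.frame mirroring a management summary table.
#' @export
managementSummary <- function(surface, categories, labels = NULL) {
  v <- as.vector(surface@values)
  ok <- is.finite(v)
  if (is(categories, "GridRaster")) {
    assertAligned(surface, categories)
    catv <- as.vector(categories@values)
  } else {
    cc <- cellCenters(surface)
    catv <- rep(NA_real_, length(v))
    for (i in seq_along(categories)) {
      inside <- pointInPolygon(cc$x, cc$y, categories[[i]])
      catv[inside] <- i
    }
    if (is.null(labels)) labels <- names(categories)
  }
  ok <- ok & !is.na(catv)
  top20 <- .topCells(v, ok, 0.20)
  top10 <- .topCells(v, ok, 0.10)
  cats <- sort(unique(catv[ok]))
  rows <- lapply(cats, function(cat) {
    sel <- which(ok & catv == cat)
    data.frame(
      category = if (!is.null(labels)) labels[match(cat, cats)] else
        as.character(cat),
      area_pct = 100 * length(sel) / sum(ok),
      top20_pct = 100 * sum(top20 %in% sel) / length(top20),
      top10_pct = 100 * sum(top10 %in% sel) / length(top10))
  })
  out <- do.call(rbind, rows)
  out$oe_ratio <- observedExpectedRatio(out$top10_pct, out$area_pct)
  out
}
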