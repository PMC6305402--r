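# Tile-based heterogeneity features.
#
# The tissue is covered by axis-aligned square tiles (edge 250/500/1000 um by
# default), anchored at the tissue bounding-box minimum. A tile enters the
# statistics when its overlap with the (exclusion-corrected) tissue is at
# least a configurable fraction of the tile area (10% by default); the
# tumor-only scope instead keeps tiles lying entirely inside the tumor
# compartment. Base features are evaluated per tile with the tile as the
# region; distances remain slide-wide. Per-tile values follow IEEE
# semantics (x/0 = Inf for x != 0, 0/0 = NaN) and non-finite values are
# filtered out before any dispersion measure is computed.

#' TileGrid: square tiling of a slide
#'
#' @slot edge tile edge length in micrometers.
#' @slot origin grid origin (minimum corner) in micrometers.
#' @slot scope \code{"entire_slide"} or \code{"tumor_only"}.
#' @slot tiles data.frame with tile bounds (\code{xmin}, \code{ymin},
#'   \code{xmax}, \code{ymax}), \code{overlap} (tile-tissue overlap, um^2)
#'   and \code{in_tumor} (tile entirely inside the tumor compartment).
#' @export
setClass("TileGrid",
  representation(edge = "numeric", origin = "numeric", scope = "character",
                 tiles = "data.frame"))

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d tiles of %g um (%s scope)\n",
              nrow(object@tiles), object@edge, object@scope))
})

#' @describeIn TileGrid retained tiles with bounds and overlap areas
#' @param object a \code{TileGrid}.
#' @export
setGeneric("gridTiles", function(object) standardGeneric("gridTiles"))
#' @describeIn TileGrid retained tiles
#' @export
setMethod("gridTiles", "TileGrid", function(object) object@tiles)

#' Build a square tile grid over a slide
#'
#' @param slide a [SlideObjects-class].
#' @param edge tile edge length in micrometers.
#' @param scope \code{"entire_slide"} keeps tiles with at least
#'   \code{overlapMin} of their area inside the tissue; \code{"tumor_only"}
#'   keeps tiles lying entirely inside the tumor compartment.
#' @param overlapMin minimum tile/tissue overlap fraction.
#' @param offset grid-origin offset (x, y) relative to the tissue
#'   bounding-box minimum, in micrometers.
#' @return A [TileGrid-class]; the grid may be empty (no qualifying tiles).
#' @export
buildGrid <- function(slide, edge, scope = c("entire_slide", "tumor_only"),
                      overlapMin = 0.1, offset = c(0, 0)) {
  scope <- match.arg(scope)
  stopifnot(edge > 0)
  r <- slideRegions(slide)
  bb <- boundingBox(r$tissue)
  origin <- c(bb[["xmin"]], bb[["ymin"]]) + offset
  nx <- max(1L, ceiling((bb[["xmax"]] - origin[1L]) / edge - 1e-9))
  ny <- max(1L, ceiling((bb[["ymax"]] - origin[2L]) / edge - 1e-9))
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  xmin <- origin[1L] + g$ix * edge
  ymin <- origin[2L] + g$iy * edge
  hasExcl <- length(asRegion(r$exclusions)) > 0L
  hasTumor <- length(asRegion(r$tumor)) > 0L
  overlap <- numeric(nrow(g))
  tumorOv <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    rect <- rectRing(xmin[i], ymin[i], xmin[i] + edge, ymin[i] + edge)
    ov <- intersectionArea(r$tissue, rect)
    if (hasExcl && ov > 0)
      ov <- ov - intersectionArea(r$tissue, r$exclusions, rect)
    overlap[i] <- max(0, ov)
    if (hasTumor) {
      tv <- intersectionArea(r$tissue, r$tumor, rect)
      if (hasExcl && tv > 0)
        tv <- tv - intersectionArea(r$tissue, r$tumor, r$exclusions, rect)
      tumorOv[i] <- max(0, tv)
    }
  }
  tileArea <- edge^2
  inTumor <- tumorOv >= tileArea * (1 - 1e-9)
  keep <- if (scope == "entire_slide") overlap >= overlapMin * tileArea
          else inTumor
  tiles <- data.frame(xmin = xmin[keep], ymin = ymin[keep],
                      xmax = xmin[keep] + edge, ymax = ymin[keep] + edge,
                      overlap = overlap[keep], in_tumor = inTumor[keep])
  rownames(tiles) <- NULL
  methods::new("TileGrid", edge = edge, origin = origin, scope = scope,
               tiles = tiles)
}

# half-open tile membership: each object belongs to exactly one grid cell
.tileIndex <- function(objects, grid) {
  t <- gridTiles(grid)
  if (nrow(t) == 0L || nrow(objects) == 0L)
    return(rep(NA_integer_, nrow(objects)))
  e <- grid@edge
  ix <- floor((objects$x - grid@origin[1L]) / e + 1e-12)
  iy <- floor((objects$y - grid@origin[2L]) / e + 1e-12)
  key <- paste(ix, iy)
  tk <- paste(round((t$xmin - grid@origin[1L]) / e),
              round((t$ymin - grid@origin[2L]) / e))
  match(key, tk)
}

# per-tile values for all base specs at once: nbase x ntiles matrix with
# IEEE non-finite semantics preserved
.perTileMatrix <- function(slide, base, grid,
                           catalog = objectSetCatalog(TRUE)) {
  tiles <- gridTiles(grid)
  nt <- nrow(tiles)
  if (nt == 0L)
    return(matrix(NA_real_, nrow(base), 0L))
  objs <- cellData(slide)
  setNames <- unique(c(base$num, base$den[!is.na(base$den)]))
  crits <- .parseCrits(base)
  M <- membershipMatrix(objs, setNames, catalog)
  refSets <- unique(unlist(lapply(crits, `[[`, "ref")))
  D <- nnDistanceToSets(objs, refSets, catalog)
  Z <- if (length(crits))
    vapply(crits, function(cr) criterionIndicator(D, cr), logical(nrow(objs)))
  else matrix(FALSE, nrow(objs), 0L)
  if (nrow(objs) == 1L) Z <- matrix(Z, nrow = 1L)
  ti <- .tileIndex(objs, grid)
  nc <- matrix(0, length(setNames), nt, dimnames = list(setNames, NULL))
  cc <- array(0, dim = c(length(setNames), length(crits), nt),
              dimnames = list(setNames, names(crits), NULL))
  for (t in seq_len(nt)) {
    mask <- !is.na(ti) & ti == t
    nc[, t] <- colSums(M & mask)
    if (length(crits))
      cc[, , t] <- crossprod(M & mask, Z)
  }
  critKey <- .critKey(base$ref, base$comb, base$dir, base$theta)
  si <- match(base$num, setNames)
  ki <- match(critKey, names(crits))
  di <- match(base$den, setNames)
  V <- matrix(NA_real_, nrow(base), nt)
  areaMm2 <- tiles$overlap / 1e6
  for (t in seq_len(nt)) {
    numCount <- ifelse(is.na(ki), nc[cbind(si, t)], cc[cbind(si, ki, t)])
    denCount <- ifelse(is.na(di), NA_real_,
                       ifelse(base$den_crit & !is.na(ki),
                              cc[cbind(di, ki, t)], nc[cbind(di, t)]))
    v <- numCount
    v[base$class == "density"] <-
      numCount[base$class == "density"] / areaMm2[t]
    isRatio <- base$class == "ratio"
    v[isRatio] <- numCount[isRatio] / denCount[isRatio]  # IEEE: Inf / NaN
    V[, t] <- v
  }
  V
}

#' Per-tile values of one base feature
#'
#' Evaluates one base feature for every tile of a grid, with the tile as the
#' region. Non-finite values (zero denominators) are preserved following
#' IEEE semantics.
#'
#' @param slide a [SlideObjects-class].
#' @param base one-row base spec as produced by the catalog enumeration, or a
#'   list with fields \code{class}, \code{num}, \code{den}, \code{ref},
#'   \code{comb}, \code{dir}, \code{theta}, \code{den_crit}.
#' @param grid a [TileGrid-class].
#' @param catalog object-set catalog.
#' @return numeric vector, one value per tile (may contain Inf/NaN).
#' @export
perTileValues <- function(slide, base, grid,
                          catalog = objectSetCatalog(TRUE)) {
  base <- as.data.frame(base, stringsAsFactors = FALSE)
  for (col in c("den", "ref", "comb", "dir"))
    if (is.null(base[[col]])) base[[col]] <- NA_character_
  if (is.null(base$theta)) base$theta <- NA_real_
  if (is.null(base$den_crit)) base$den_crit <- FALSE
  as.vector(.perTileMatrix(slide, base, grid, catalog))
}

#' Coefficient of variation of tile values
#'
#' Sample standard deviation (n - 1 normalization) divided by the arithmetic
#' mean, after filtering non-finite values.
#'
#' @param values per-tile feature values.
#' @return the COV, or \code{NA} when fewer than 2 finite values remain or
#'   the mean is zero.
#' @export
hetCOV <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  stats::sd(v) / m
}

#' Quartile coefficient of dispersion of tile values
#'
#' (p75 - p25) / (p75 + p25) with linear-interpolation percentiles, after
#' filtering non-finite values.
#'
#' @inheritParams hetCOV
#' @return the QCD, or \code{NA} when fewer than 2 finite values remain or
#'   p75 + p25 is zero.
#' @export
hetQCD <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) return(NA_real_)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1L] + q[2L] == 0) return(NA_real_)
  (q[2L] - q[1L]) / (q[2L] + q[1L])
}

#' Relative percentile of tile values
#'
#' A fixed percentile (3, 5, 10, 90, 95 or 97) divided by the median, with
#' linear-interpolation percentiles, after filtering non-finite values.
#'
#' @inheritParams hetCOV
#' @param p percentile in \{3, 5, 10, 90, 95, 97\}.
#' @return the relative percentile, or \code{NA} when fewer than 2 finite
#'   values remain or the median is zero.
#' @export
hetRP <- function(values, p) {
  stopifnot(p %in% c(3, 5, 10, 90, 95, 97))
  v <- values[is.finite(values)]
  if (length(v) < 2L) return(NA_real_)
  med <- stats::median(v)
  if (med == 0) return(NA_real_)
  stats::quantile(v, p / 100, names = FALSE, type = 7) / med
}

# all 8 measures of one value vector, in .hetMeasures order
.allMeasures <- function(v) {
  f <- v[is.finite(v)]
  if (length(f) < 2L) return(rep(NA_real_, 8L))
  q <- stats::quantile(f, c(0.03, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90,
                            0.95, 0.97), names = FALSE, type = 7)
  m <- mean(f)
  med <- q[5L]
  cov <- if (m == 0) NA_real_ else stats::sd(f) / m
  qcd <- if (q[4L] + q[6L] == 0) NA_real_ else
    (q[6L] - q[4L]) / (q[6L] + q[4L])
  rp <- if (med == 0) rep(NA_real_, 6L) else q[c(1L, 2L, 3L, 7L, 8L, 9L)] / med
  c(cov, qcd, rp)
}

#' Compute all heterogeneity features of a catalog for one slide
#'
#' For every tile edge and scope, evaluates all per-region base features per
#' tile and summarizes the tile values with the 8 dispersion measures.
#' Features of an empty grid (e.g. tumor-only scope without tumor) are
#' unavailable with reason \code{region_missing}; measures undefined after
#' non-finite filtering (fewer than 2 finite tile values, zero mean/median/
#' quartile sum) are unavailable with reason \code{nonfinite}.
#'
#' @param slide a [SlideObjects-class].
#' @param config an [catalogConfig()] object.
#' @param hetCat optionally a pre-built [heterogeneityCatalog()].
#' @return data.frame \code{feature_id}, \code{value}, \code{reason} aligned
#'   with the heterogeneity catalog order.
#' @export
computeHeterogeneityFeatures <- function(slide, config = catalogConfig(),
                                         hetCat = heterogeneityCatalog(config)) {
  base <- baseCatalog(config)
  setCat <- c(config$typeCatalog,
              objectSetCatalog(TRUE)[setdiff(names(objectSetCatalog(TRUE)),
                                             names(config$typeCatalog))])
  res <- list()
  for (edge in config$tileEdges) {
    for (scope in config$scopes) {
      grid <- buildGrid(slide, edge, scope, config$overlapMin,
                        config$gridOffset)
      key <- paste0(edge, "|", scope)
      if (nrow(gridTiles(grid)) == 0L) {
        res[[key]] <- matrix(NA_real_, nrow(base), 8L,
                             dimnames = list(NULL, .hetMeasures))
        attr(res[[key]], "empty") <- TRUE
        next
      }
      V <- .perTileMatrix(slide, base, grid, setCat)
      stats8 <- t(apply(V, 1L, .allMeasures))
      colnames(stats8) <- .hetMeasures
      res[[key]] <- stats8
    }
  }
  idx <- cbind(match(hetCat$base_id, base$base_id),
               match(hetCat$measure, .hetMeasures))
  key <- paste0(hetCat$edge, "|", hetCat$scope)
  value <- numeric(nrow(hetCat))
  reason <- character(nrow(hetCat))
  for (k in unique(key)) {
    sel <- key == k
    value[sel] <- res[[k]][idx[sel, , drop = FALSE]]
    reason[sel] <- if (isTRUE(attr(res[[k]], "empty"))) "region_missing"
                   else "none"
  }
  reason[is.na(value) & reason == "none"] <- "nonfinite"
  data.frame(feature_id = hetCat$feature_id, value = value, reason = reason,
             stringsAsFactors = FALSE)
}
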