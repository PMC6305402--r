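# Feature catalog enumeration.
#
# Global features come in two groups per tissue region (entire / tumor /
# non-tumor):
#   density-based: object counts, densities (1/mm^2), and ratios of counts
#     over a configurable list of ordered set pairs;
#   distance-based: counts and ratios restricted by a cell-to-cell distance
#     criterion "nearest member of the reference combination M is <= / > theta",
#     with OR/AND combination over M and theta from a fixed grid.
# Heterogeneity features evaluate each per-region base feature over square
# tile grids and summarize the tile values with 8 dispersion measures.
#
# The published supplementary lists of 156 ratio pairs and 279 distance
# combinations are not available; the defaults here are documented canonical
# enumerations of exactly those sizes, so that the catalog census
# (528 / 5,859 / 8,448 / 102,192; grand total 108,579) is reproduced.

.thetaGrid <- c(15, 20, 25, 30, 35, 50, 100)
.hetMeasures <- c("COV", "QCD", "RP3", "RP5", "RP10", "RP90", "RP95", "RP97")
.regions3 <- c("entire", "tumor", "non_tumor")

#' Default ratio pairs
#'
#' All ordered pairs of distinct sets over the extended 13-set catalog
#' (the 10 default sets plus all-cells, all-proliferating,
#' all-non-proliferating), i.e. 13 x 12 = 156 pairs.
#' @return data.frame with columns \code{num}, \code{den}.
#' @export
defaultRatioPairs <- function() {
  sets <- names(objectSetCatalog(extended = TRUE))
  g <- expand.grid(den = sets, num = sets, stringsAsFactors = FALSE)
  g <- g[g$num != g$den, c("num", "den")]
  rownames(g) <- NULL
  g
}

# Canonical enumeration of distance-based feature combinations (theta is
# added later from the grid). Ordered by increasing structural complexity:
#   1. fractions with a single reference set: #{w in A : crit} / #A
#   2. criterion counts with a single reference set
#   3. fractions with two-set references (OR then AND)
#   4. criterion counts with two-set references
#   5. general ratios (num != den) with single references, criterion
#      applied to the numerator only or to both counts
# The default size 279 covers block 1 and most of block 2; the enumeration
# guarantees that the verification feature (fraction of Ki67 within theta of
# the closest proliferating CD8) is always present.
defaultDistanceCombos <- function(n = 279) {
  sets <- names(objectSetCatalog())
  atoms <- c("Ki67", "CD4_prolif", "CD4_nonprolif", "CD8_prolif",
             "CD8_nonprolif", "CD4_any", "CD8_any")[c(1, 6, 2, 3, 7, 4, 5)]
  blocks <- list()
  combo <- function(class, num, den, ref, comb, dir, den_crit)
    data.frame(class = class, num = num, den = den, ref = ref, comb = comb,
               dir = dir, den_crit = den_crit, stringsAsFactors = FALSE)
  b1 <- do.call(rbind, lapply(sets, function(a)
    do.call(rbind, lapply(atoms, function(r)
      rbind(combo("ratio", a, a, r, "OR", "LE", FALSE),
            combo("ratio", a, a, r, "OR", "GT", FALSE))))))
  b2 <- b1
  b2$class <- "count"; b2$den <- NA_character_; b2$den_crit <- FALSE
  pairs <- t(utils::combn(atoms, 2L))
  refPairs <- paste(pairs[, 1L], pairs[, 2L], sep = "+")
  b3 <- do.call(rbind, lapply(sets, function(a)
    do.call(rbind, lapply(refPairs, function(r)
      do.call(rbind, lapply(c("OR", "AND"), function(cb)
        rbind(combo("ratio", a, a, r, cb, "LE", FALSE),
              combo("ratio", a, a, r, cb, "GT", FALSE))))))))
  b4 <- b3
  b4$class <- "count"; b4$den <- NA_character_; b4$den_crit <- FALSE
  op <- expand.grid(den = sets, num = sets, stringsAsFactors = FALSE)
  op <- op[op$num != op$den, ]
  b5 <- do.call(rbind, lapply(seq_len(nrow(op)), function(i)
    do.call(rbind, lapply(atoms, function(r)
      do.call(rbind, lapply(c("LE", "GT"), function(d)
        rbind(combo("ratio", op$num[i], op$den[i], r, "OR", d, FALSE),
              combo("ratio", op$num[i], op$den[i], r, "OR", d, TRUE))))))))
  universe <- rbind(b1, b2, b3, b4, b5)
  if (n > nrow(universe))
    stop("at most ", nrow(universe), " distance combinations are enumerable")
  out <- universe[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalog configuration
#'
#' Bundles everything that determines the feature catalog and the
#' heterogeneity evaluation. Defaults reproduce the published census: 156
#' ratio pairs, 279 distance combinations x 7 thresholds (= 1,953 per
#' region), tile edges 250/500/1000 um, 10% minimum tile overlap, and the
#' OPM screening threshold 0.6.
#'
#' @param typeCatalog named list of object-set definitions (10 by default).
#' @param ratioPairs data.frame \code{num}, \code{den} of ratio pairs.
#' @param distanceCombos data.frame of distance-based combinations
#'   (see \code{defaultDistanceCombos}).
#' @param nDistanceCombos convenience: size of the default enumeration used
#'   when \code{distanceCombos} is not given.
#' @param thresholds distance-threshold grid in micrometers.
#' @param regions tissue regions to enumerate.
#' @param tileEdges tile edge lengths in micrometers.
#' @param scopes heterogeneity evaluation scopes.
#' @param measures heterogeneity measures.
#' @param overlapMin minimum tile/tissue overlap fraction for a tile to enter
#'   the statistics.
#' @param gridOffset (x, y) offset of the tile-grid origin relative to the
#'   tissue bounding-box minimum, in micrometers.
#' @param opmThreshold screening threshold: features with OPM at or above it
#'   are flagged potentially predictive.
#' @return list of class \code{icCatalogConfig}.
#' @export
catalogConfig <- function(typeCatalog = objectSetCatalog(),
                          ratioPairs = defaultRatioPairs(),
                          distanceCombos = NULL,
                          nDistanceCombos = 279,
                          thresholds = .thetaGrid,
                          regions = .regions3,
                          tileEdges = c(250, 500, 1000),
                          scopes = c("entire_slide", "tumor_only"),
                          measures = .hetMeasures,
                          overlapMin = 0.1,
                          gridOffset = c(0, 0),
                          opmThreshold = 0.6) {
  if (is.null(distanceCombos))
    distanceCombos <- defaultDistanceCombos(nDistanceCombos)
  structure(list(typeCatalog = typeCatalog, ratioPairs = ratioPairs,
                 distanceCombos = distanceCombos, thresholds = thresholds,
                 regions = regions, tileEdges = tileEdges, scopes = scopes,
                 measures = measures, overlapMin = overlapMin,
                 gridOffset = gridOffset, opmThreshold = opmThreshold),
            class = "icCatalogConfig")
}

.fmtTheta <- function(theta) sprintf("%03d", as.integer(theta))

.critKey <- function(ref, comb, dir, theta) {
  ifelse(is.na(theta), "-",
         paste(ref, comb, dir, .fmtTheta(theta), sep = ";"))
}

.globalId <- function(region, class, num, den, ref, comb, dir, theta,
                      den_crit) {
  paste0("global|", region, "|", class, "|num=", num,
         "|den=", ifelse(is.na(den), "-", den),
         "|crit=", .critKey(ref, comb, dir, theta),
         ifelse(is.na(theta), "", paste0("|dc=", as.integer(den_crit))))
}

#' Enumerate the global feature catalog
#'
#' @param config an [catalogConfig()] object.
#' @return data.frame, one row per feature spec, with the canonical
#'   \code{feature_id} (unique, lexicographically ordered), \code{group}
#'   (density / distance), \code{class} (count / density / ratio),
#'   \code{region}, the numerator/denominator sets, and the criterion fields
#'   (\code{ref}, \code{comb}, \code{dir}, \code{theta}, \code{den_crit}).
#' @examples
#' nrow(featureCatalog(catalogConfig()))  # 6387
#' @export
featureCatalog <- function(config = catalogConfig()) {
  sets <- names(config$typeCatalog)
  dens <- do.call(rbind, lapply(config$regions, function(rg) {
    counts <- data.frame(group = "density", class = "count", region = rg,
                         num = sets, den = NA_character_,
                         stringsAsFactors = FALSE)
    densities <- counts; densities$class <- "density"
    out <- rbind(counts, densities)
    if (nrow(config$ratioPairs) > 0L)
      out <- rbind(out, data.frame(group = "density", class = "ratio",
                                   region = rg, num = config$ratioPairs$num,
                                   den = config$ratioPairs$den,
                                   stringsAsFactors = FALSE))
    out$ref <- NA_character_; out$comb <- NA_character_
    out$dir <- NA_character_; out$theta <- NA_real_; out$den_crit <- FALSE
    out
  }))
  cmb <- config$distanceCombos
  dist <- do.call(rbind, lapply(config$regions, function(rg)
    do.call(rbind, lapply(config$thresholds, function(th) {
      out <- data.frame(group = "distance", class = cmb$class, region = rg,
                        num = cmb$num, den = cmb$den, ref = cmb$ref,
                        comb = cmb$comb, dir = cmb$dir, theta = th,
                        den_crit = cmb$den_crit, stringsAsFactors = FALSE)
      out
    }))))
  cat <- rbind(dens, dist)
  cat$feature_id <- .globalId(cat$region, cat$class, cat$num, cat$den,
                              cat$ref, cat$comb, cat$dir, cat$theta,
                              cat$den_crit)
  if (anyDuplicated(cat$feature_id))
    stop("duplicate canonical feature keys in catalog")
  cat <- cat[order(cat$feature_id, method = "radix"), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

# per-region base forms: the global catalog with the region dimension dropped
baseCatalog <- function(config = catalogConfig()) {
  cat <- featureCatalog(config)
  base <- cat[cat$region == config$regions[[1L]], , drop = FALSE]
  base$region <- NULL
  base$base_id <- sub("^global\\|[^|]+\\|", "", base$feature_id)
  base$feature_id <- NULL
  base <- base[order(base$base_id, method = "radix"), , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Enumerate the heterogeneity feature catalog
#'
#' One spec per (per-region base feature, measure, tile edge, scope).
#' @param config an [catalogConfig()] object.
#' @return data.frame with the base-spec columns plus \code{measure},
#'   \code{edge}, \code{scope} and the canonical \code{feature_id}.
#' @examples
#' nrow(heterogeneityCatalog(catalogConfig()))  # 102192
#' @export
heterogeneityCatalog <- function(config = catalogConfig()) {
  base <- baseCatalog(config)
  grid <- expand.grid(scope = config$scopes, edge = config$tileEdges,
                      measure = config$measures, b = seq_len(nrow(base)),
                      stringsAsFactors = FALSE)
  out <- base[grid$b, , drop = FALSE]
  out$measure <- grid$measure
  out$edge <- grid$edge
  out$scope <- grid$scope
  out$feature_id <- paste0("het|", out$measure, "|e=", sprintf("%04d", out$edge),
                           "|s=", out$scope, "|", out$base_id)
  if (anyDuplicated(out$feature_id))
    stop("duplicate canonical feature keys in heterogeneity catalog")
  out <- out[order(out$feature_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalog census
#'
#' Feature counts by class group, in the layout of the published overview
#' table (global vs heterogeneity, density- vs distance-based).
#'
#' @param config an [catalogConfig()] object.
#' @return data.frame with rows global / heterogeneity / sum and columns
#'   density_based, distance_based, sum.
#' @export
catalogCensus <- function(config = catalogConfig()) {
  g <- featureCatalog(config)
  h <- heterogeneityCatalog(config)
  gd <- sum(g$group == "density"); gx <- sum(g$group == "distance")
  hd <- sum(h$group == "density"); hx <- sum(h$group == "distance")
  data.frame(class = c("global", "heterogeneity", "sum"),
             density_based = c(gd, hd, gd + hd),
             distance_based = c(gx, hx, gx + hx),
             sum = c(gd + gx, hd + hx, gd + gx + hd + hx))
}
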