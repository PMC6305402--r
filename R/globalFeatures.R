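# Global density- and distance-based features.
#
# All distances are Euclidean, computed slide-wide (distance criteria ignore
# region and tile boundaries). A cell is never its own nearest neighbour:
# when the query object belongs to the reference set, its zero self-distance
# is excluded. The nearest-neighbour distance to an empty reference set is
# +Inf, so "<= theta" criteria count 0 and "> theta" criteria count all.

# n x k matrix of nearest-neighbour distances from every object to each named
# set (self-excluded). Exact, vectorized in chunks; no spatial index is used.
nnDistanceToSets <- function(objects, setNames,
                             catalog = objectSetCatalog(TRUE)) {
  n <- nrow(objects)
  D <- matrix(Inf, n, length(setNames),
              dimnames = list(NULL, setNames))
  if (n == 0L || length(setNames) == 0L) return(D)
  M <- membershipMatrix(objects, setNames, catalog)
  x <- objects$x; y <- objects$y
  for (k in seq_along(setNames)) {
    ref <- which(M[, k])
    m <- length(ref)
    if (m == 0L) next
    rx <- x[ref]; ry <- y[ref]
    chunk <- max(1L, floor(4e6 / m))
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      qi <- s:e
      d2 <- outer(x[qi], rx, "-")^2 + outer(y[qi], ry, "-")^2
      selfrow <- which(M[qi, k])
      if (length(selfrow))
        d2[cbind(selfrow, match(qi[selfrow], ref))] <- Inf
      if (m == 1L) {
        D[qi, k] <- sqrt(d2[, 1L])
      } else {
        D[qi, k] <- sqrt(d2[cbind(seq_along(qi),
                                  max.col(-d2, ties.method = "first"))])
      }
    }
  }
  D
}

#' Distance criterion
#'
#' A rule restricting a count to objects whose nearest-neighbour distances to
#' reference sets satisfy a threshold comparison: direction \code{"LE"} keeps
#' objects with distance <= theta, \code{"GT"} those with distance > theta;
#' with several reference sets the per-set comparisons are combined with
#' \code{"OR"} or \code{"AND"}.
#'
#' @param ref character vector of reference set names (or a single
#'   "a+b"-joined string).
#' @param dir \code{"LE"} or \code{"GT"}.
#' @param theta threshold in micrometers, from the catalog grid
#'   15/20/25/30/35/50/100 in the default configuration.
#' @param comb \code{"OR"} or \code{"AND"} (irrelevant for one set).
#' @return list of class \code{icDistanceCriterion}.
#' @export
distanceCriterion <- function(ref, dir = c("LE", "GT"), theta,
                              comb = c("OR", "AND")) {
  dir <- match.arg(dir); comb <- match.arg(comb)
  ref <- unlist(strsplit(ref, "+", fixed = TRUE))
  stopifnot(length(ref) >= 1L, is.finite(theta), theta > 0)
  structure(list(ref = ref, comb = comb, dir = dir, theta = theta),
            class = "icDistanceCriterion")
}

# logical indicator over objects for one criterion, given the NN-distance
# matrix D (columns named by reference set)
criterionIndicator <- function(D, crit) {
  sub <- D[, crit$ref, drop = FALSE]
  cmp <- if (crit$dir == "LE") sub <= crit$theta else sub > crit$theta
  if (ncol(cmp) == 1L) as.vector(cmp)
  else if (crit$comb == "OR") rowSums(cmp) > 0L
  else rowSums(cmp) == ncol(cmp)
}

.regionMask <- function(slide, region) {
  comp <- cellData(slide)$compartment
  switch(region,
         entire = rep(TRUE, length(comp)),
         tumor = comp == "tumor",
         non_tumor = comp == "non_tumor",
         stop("unknown region: ", region))
}

.regionAreaMm2 <- function(slide, region) {
  unname(regionAreas(slide)[[region]])
}

#' Count objects of a set in a region
#'
#' @param slide a [SlideObjects-class].
#' @param set object-set name or definition.
#' @param region \code{"entire"}, \code{"tumor"}, or \code{"non_tumor"}.
#' @param catalog set catalog for name resolution.
#' @return integer count, or \code{NA} when the region has zero area.
#' @export
countObjects <- function(slide, set, region = "entire",
                         catalog = objectSetCatalog(TRUE)) {
  if (.regionAreaMm2(slide, region) <= 0) return(NA_integer_)
  sum(setMembership(cellData(slide), set, catalog) &
        .regionMask(slide, region))
}

#' Object density in a region (1 per square millimeter)
#' @inheritParams countObjects
#' @return density in 1/mm^2, or \code{NA} when the region has zero area.
#' @export
objectDensity <- function(slide, set, region = "entire",
                          catalog = objectSetCatalog(TRUE)) {
  a <- .regionAreaMm2(slide, region)
  if (a <= 0) return(NA_real_)
  countObjects(slide, set, region, catalog) / a
}

#' Ratio of two object counts in a region
#' @inheritParams countObjects
#' @param numSet,denSet numerator and denominator set names.
#' @return the count ratio; \code{NA} when the region is missing or the
#'   denominator count is zero (non-finite value).
#' @export
countRatio <- function(slide, numSet, denSet, region = "entire",
                       catalog = objectSetCatalog(TRUE)) {
  a <- countObjects(slide, numSet, region, catalog)
  b <- countObjects(slide, denSet, region, catalog)
  if (is.na(a) || is.na(b) || b == 0L) return(NA_real_)
  a / b
}

#' Nearest-neighbour distance to a reference set
#'
#' Distance in micrometers from each retained object of the slide to the
#' closest member of the reference set, excluding the object itself when it
#' belongs to the set. \code{Inf} when the set is empty on the slide.
#'
#' @inheritParams countObjects
#' @return numeric vector, one entry per retained object.
#' @export
nnDistance <- function(slide, set, catalog = objectSetCatalog(TRUE)) {
  if (is.character(set)) setName <- set
  else { setName <- "query"; catalog <- c(catalog, list(query = set)) }
  as.vector(nnDistanceToSets(cellData(slide), setName, catalog))
}

#' Count objects satisfying a distance criterion
#'
#' Counts the objects of a set in a region whose nearest-neighbour distances
#' to the criterion's reference sets satisfy the threshold comparison.
#' Distances are computed slide-wide and do not respect region boundaries.
#'
#' @inheritParams countObjects
#' @param criterion an [distanceCriterion()] object.
#' @return integer count, or \code{NA} when the region has zero area.
#' @export
countWithCriterion <- function(slide, set, criterion, region = "entire",
                               catalog = objectSetCatalog(TRUE)) {
  if (.regionAreaMm2(slide, region) <= 0) return(NA_integer_)
  objs <- cellData(slide)
  D <- nnDistanceToSets(objs, criterion$ref, catalog)
  sum(setMembership(objs, set, catalog) & .regionMask(slide, region) &
        criterionIndicator(D, criterion))
}

#' Distance-restricted count ratio
#'
#' Ratio of two criterion-restricted counts. The identical criterion is
#' applied to the numerator and, when \code{denCriterion = TRUE}, also to the
#' denominator; otherwise the denominator is the unrestricted count (the
#' "fraction" form when both sets coincide).
#'
#' @inheritParams countRatio
#' @param criterion an [distanceCriterion()] object.
#' @param denCriterion apply the criterion to the denominator count as well.
#' @return the ratio; \code{NA} when the region is missing or the value is
#'   non-finite (zero denominator).
#' @export
distanceRatio <- function(slide, numSet, denSet, criterion,
                          region = "entire", denCriterion = FALSE,
                          catalog = objectSetCatalog(TRUE)) {
  a <- countWithCriterion(slide, numSet, criterion, region, catalog)
  b <- if (denCriterion)
    countWithCriterion(slide, denSet, criterion, region, catalog)
  else countObjects(slide, denSet, region, catalog)
  if (is.na(a) || is.na(b) || b == 0L) return(NA_real_)
  a / b
}

# --- vectorized whole-catalog evaluation -----------------------------------

# counts for all (set, criterion-or-none, region) combinations used by a
# catalog; returns list(nc = sets x regions matrix, cc = array or NULL)
.countTables <- function(slide, setNames, crits, regions,
                         catalog = objectSetCatalog(TRUE)) {
  objs <- cellData(slide)
  n <- nrow(objs)
  M <- membershipMatrix(objs, setNames, catalog)
  refSets <- unique(unlist(lapply(crits, `[[`, "ref")))
  D <- nnDistanceToSets(objs, refSets, catalog)
  Z <- if (length(crits))
    vapply(crits, function(cr) criterionIndicator(D, cr), logical(n))
  else matrix(FALSE, n, 0L)
  if (n == 1L) Z <- matrix(Z, nrow = 1L)
  if (n == 0L) Z <- matrix(FALSE, 0L, length(crits))
  nc <- matrix(0, length(setNames), length(regions),
               dimnames = list(setNames, regions))
  cc <- array(0, dim = c(length(setNames), length(crits), length(regions)),
              dimnames = list(setNames, names(crits), regions))
  for (r in seq_along(regions)) {
    mask <- .regionMask(slide, regions[[r]])
    nc[, r] <- colSums(M & mask)
    if (length(crits))
      cc[, , r] <- crossprod(M & mask, Z)
  }
  list(nc = nc, cc = cc)
}

.parseCrits <- function(cat) {
  keys <- unique(.critKey(cat$ref, cat$comb, cat$dir, cat$theta))
  keys <- keys[keys != "-"]
  crits <- lapply(keys, function(k) {
    p <- strsplit(k, ";", fixed = TRUE)[[1L]]
    distanceCriterion(p[1L], p[3L], as.numeric(p[4L]), p[2L])
  })
  names(crits) <- keys
  crits
}

#' Compute all global features of a catalog for one slide
#'
#' Evaluates every spec of the global feature catalog on one slide. Features
#' of a region with zero area (e.g. the tumor compartment of a slide without
#' tumor annotation) are unavailable with reason \code{region_missing};
#' ratios with a zero denominator count are unavailable with reason
#' \code{nonfinite}.
#'
#' @param slide a [SlideObjects-class].
#' @param config an [catalogConfig()] object.
#' @param cat optionally a pre-built [featureCatalog()] for \code{config}.
#' @return data.frame \code{feature_id}, \code{value}, \code{reason}
#'   (\code{none} / \code{region_missing} / \code{nonfinite}), aligned with
#'   the catalog order.
#' @export
computeGlobalFeatures <- function(slide, config = catalogConfig(),
                                  cat = featureCatalog(config)) {
  setNames <- unique(c(cat$num, cat$den[!is.na(cat$den)]))
  crits <- .parseCrits(cat)
  tb <- .countTables(slide, setNames, crits, config$regions,
                     c(config$typeCatalog,
                       objectSetCatalog(TRUE)[setdiff(
                         names(objectSetCatalog(TRUE)),
                         names(config$typeCatalog))]))
  areas <- regionAreas(slide)
  critKey <- .critKey(cat$ref, cat$comb, cat$dir, cat$theta)
  ri <- match(cat$region, config$regions)
  si <- match(cat$num, setNames)
  ki <- match(critKey, names(crits))          # NA for criterion-free
  numCount <- ifelse(is.na(ki), tb$nc[cbind(si, ri)],
                     tb$cc[cbind(si, ki, ri)])
  di <- match(cat$den, setNames)              # NA for count/density
  denCount <- ifelse(is.na(di), NA_real_,
                     ifelse(cat$den_crit & !is.na(ki),
                            tb$cc[cbind(di, ki, ri)],
                            tb$nc[cbind(di, ri)]))
  regionArea <- unname(unlist(areas))[ri]
  value <- numeric(nrow(cat))
  value[cat$class == "count"] <- numCount[cat$class == "count"]
  value[cat$class == "density"] <-
    numCount[cat$class == "density"] / regionArea[cat$class == "density"]
  isRatio <- cat$class == "ratio"
  value[isRatio] <- numCount[isRatio] / denCount[isRatio]
  reason <- rep("none", nrow(cat))
  nonfin <- isRatio & (is.na(denCount) | denCount == 0)
  reason[nonfin] <- "nonfinite"
  value[nonfin] <- NA_real_
  missing <- regionArea <= 0
  reason[missing] <- "region_missing"
  value[missing] <- NA_real_
  data.frame(feature_id = cat$feature_id, value = value, reason = reason,
             stringsAsFactors = FALSE)
}
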