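# Independent brute-force oracles. These deliberately avoid the package's
# engine machinery (chunked NN computation, indicator matrices, crossprod
# count tables): everything is derived from a full O(n^2) distance matrix
# and explicit set logic.

oracleDistMatrix <- function(objects) {
  d <- as.matrix(stats::dist(objects[, c("x", "y")]))
  diag(d) <- Inf
  d
}

# nearest-neighbour distance of every object to a member set (self-excluded)
oracleNN <- function(objects, member) {
  d <- oracleDistMatrix(objects)
  if (!any(member)) return(rep(Inf, nrow(objects)))
  unname(apply(d[, member, drop = FALSE], 1L, min))
}

# indicator of a distance criterion from first principles
oracleCriterion <- function(objects, refMembers, comb, dir, theta) {
  per <- vapply(refMembers, function(m) {
    nn <- oracleNN(objects, m)
    if (dir == "LE") nn <= theta else nn > theta
  }, logical(nrow(objects)))
  if (length(refMembers) == 1L) return(as.vector(per))
  if (comb == "OR") rowSums(per) > 0L else rowSums(per) == length(refMembers)
}

# value of one global catalog row computed from scratch
oracleGlobalValue <- function(slide, row, areas = regionAreas(slide)) {
  o <- cellData(slide)
  cat13 <- objectSetCatalog(TRUE)
  mask <- switch(row$region,
                 entire = rep(TRUE, nrow(o)),
                 tumor = o$compartment == "tumor",
                 non_tumor = o$compartment == "non_tumor")
  area <- areas[[row$region]]
  if (area <= 0) return(NA_real_)
  crit <- NULL
  if (!is.na(row$theta)) {
    refs <- strsplit(row$ref, "+", fixed = TRUE)[[1L]]
    crit <- oracleCriterion(o, lapply(refs, function(s)
      setMembership(o, s, cat13)), row$comb, row$dir, row$theta)
  }
  numMem <- setMembership(o, row$num, cat13)
  num <- if (is.null(crit)) sum(numMem & mask) else sum(numMem & mask & crit)
  if (row$class == "count") return(num)
  if (row$class == "density") return(num / area)
  denMem <- setMembership(o, row$den, cat13)
  den <- if (!is.null(crit) && isTRUE(row$den_crit))
    sum(denMem & mask & crit) else sum(denMem & mask)
  if (den == 0) return(NA_real_)
  num / den
}

# per-tile values of one base spec, recomputed from scratch over tile bounds
oraclePerTile <- function(slide, row, grid) {
  o <- cellData(slide)
  cat13 <- objectSetCatalog(TRUE)
  t <- gridTiles(grid)
  crit <- NULL
  if (!is.na(row$theta)) {
    refs <- strsplit(row$ref, "+", fixed = TRUE)[[1L]]
    crit <- oracleCriterion(o, lapply(refs, function(s)
      setMembership(o, s, cat13)), row$comb, row$dir, row$theta)
  } else crit <- rep(TRUE, nrow(o))
  numMem <- setMembership(o, row$num, cat13)
  denMem <- if (!is.na(row$den)) setMembership(o, row$den, cat13)
  vapply(seq_len(nrow(t)), function(i) {
    inTile <- o$x >= t$xmin[i] & o$x < t$xmax[i] &
      o$y >= t$ymin[i] & o$y < t$ymax[i]
    num <- sum(numMem & inTile & crit)
    if (row$class == "count") return(as.numeric(num))
    if (row$class == "density") return(num / (t$overlap[i] / 1e6))
    den <- if (isTRUE(row$den_crit)) sum(denMem & inTile & crit)
    else sum(denMem & inTile)
    num / den  # IEEE: Inf and NaN preserved
  }, 0)
}

# dispersion measures from their defining formulas (declared conventions:
# linear-interpolation percentiles, sample sd)
oracleMeasure <- function(values, measure) {
  f <- values[is.finite(values)]
  if (length(f) < 2L) return(NA_real_)
  pct <- function(p) {
    s <- sort(f); h <- (length(s) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  switch(measure,
    COV = { m <- mean(f)
            if (m == 0) NA_real_
            else sqrt(sum((f - m)^2) / (length(f) - 1)) / m },
    QCD = { q1 <- pct(0.25); q3 <- pct(0.75)
            if (q1 + q3 == 0) NA_real_ else (q3 - q1) / (q3 + q1) },
    { p <- as.numeric(sub("RP", "", measure)) / 100
      med <- pct(0.5)
      if (med == 0) NA_real_ else pct(p) / med })
}

# Monte-Carlo area of the intersection of regions within a bounding box
mcIntersectionArea <- function(regions, bbox, n = 2e5, seed = 1) {
  set.seed(seed)
  x <- stats::runif(n, bbox[1L], bbox[3L])
  y <- stats::runif(n, bbox[2L], bbox[4L])
  inAll <- Reduce(`&`, lapply(regions, function(r) pointsInRegion(x, y, r)))
  mean(inAll) * (bbox[3L] - bbox[1L]) * (bbox[4L] - bbox[2L])
}
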