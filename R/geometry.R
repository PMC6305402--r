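# Planar polygon primitives for tissue-region handling.
#
# A "ring" is an n x 2 numeric matrix of vertices (not closed: first vertex is
# not repeated at the end). A "polygon" is list(outer = ring, holes = list of
# rings). A "region" is a list of polygons whose outers are pairwise disjoint
# (holes lie inside their outer), which is how slide annotations are drawn.
# All coordinates are micrometers; areas are returned in square micrometers
# unless noted otherwise.

.geom_tol <- 1e-7

#' Construct a ring matrix
#'
#' @param x,y numeric vertex coordinates in micrometers.
#' @return An n x 2 matrix usable as a polygon ring.
#' @examples
#' ring(c(0, 1, 1, 0) * 1000, c(0, 0, 1, 1) * 1000)
#' @export
ring <- function(x, y) {
  m <- cbind(as.numeric(x), as.numeric(y))
  normalizeRing(m)
}

normalizeRing <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L)
    stop("a ring must be an n x 2 matrix")
  n <- nrow(m)
  if (n >= 4L && all(abs(m[1L, ] - m[n, ]) < .geom_tol))
    m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L)
    stop("a ring needs at least 3 distinct vertices")
  if (any(!is.finite(m)))
    stop("ring coordinates must be finite")
  m
}

#' Axis-aligned rectangle ring
#' @param xmin,ymin,xmax,ymax rectangle bounds in micrometers.
#' @return A 4 x 2 ring matrix (counter-clockwise).
#' @export
rectRing <- function(xmin, ymin, xmax, ymax) {
  ring(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Assemble a region from rings
#'
#' @param outer outer boundary ring.
#' @param holes optional list of hole rings fully contained in \code{outer}.
#' @return A region (list of one polygon).
#' @export
polygonRegion <- function(outer, holes = list()) {
  list(list(outer = normalizeRing(outer),
            holes = lapply(holes, normalizeRing)))
}

asRegion <- function(x) {
  if (is.null(x)) return(list())
  if (is.matrix(x)) return(polygonRegion(x))
  if (is.list(x) && !is.null(x$outer)) return(list(x))
  x
}

signedRingArea <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
}

#' Area of a region
#' @param region a region (list of polygons with optional holes).
#' @return Area in square micrometers.
#' @export
regionArea <- function(region) {
  region <- asRegion(region)
  if (length(region) == 0L) return(0)
  sum(vapply(region, function(p) {
    a <- abs(signedRingArea(p$outer))
    if (length(p$holes))
      a <- a - sum(vapply(p$holes, function(h) abs(signedRingArea(h)), 0))
    a
  }, 0))
}

ccw <- function(ring) {
  if (signedRingArea(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

# Sutherland-Hodgman: clip an arbitrary simple subject ring against a convex
# clip ring. Returns a ring matrix (possibly with < 3 rows when empty).
clipConvex <- function(subject, clip) {
  clip <- ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    s <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    inside <- s >= -.geom_tol
    n <- nrow(out)
    nxt <- c(2:n, 1L)[seq_len(n)]
    res_x <- numeric(0); res_y <- numeric(0)
    for (j in seq_len(n)) {
      k <- nxt[j]
      if (inside[j]) {
        res_x <- c(res_x, out[j, 1L]); res_y <- c(res_y, out[j, 2L])
      }
      if (xor(inside[j], inside[k])) {
        # intersection of segment j->k with the clip edge line
        t <- s[j] / (s[j] - s[k])
        res_x <- c(res_x, out[j, 1L] + t * (out[k, 1L] - out[j, 1L]))
        res_y <- c(res_y, out[j, 2L] + t * (out[k, 2L] - out[j, 2L]))
      }
    }
    out <- cbind(res_x, res_y)
  }
  out
}

# Ear-clipping triangulation of a simple ring. Returns a list of 3 x 2
# matrices. Tolerant of collinear vertices (degenerate ears are dropped).
triangulateRing <- function(ring) {
  ring <- ccw(normalizeRing(ring))
  idx <- seq_len(nrow(ring))
  tris <- list()
  scale2 <- max(abs(ring)) ^ 2 + 1
  cross2 <- function(o, a, b)
    (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
  guard <- 0L
  while (length(idx) > 3L) {
    n <- length(idx)
    clipped <- FALSE
    for (j in seq_len(n)) {
      ip <- idx[if (j == 1L) n else j - 1L]
      iv <- idx[j]
      inx <- idx[if (j == n) 1L else j + 1L]
      a <- ring[ip, ]; b <- ring[iv, ]; cc <- ring[inx, ]
      cr <- cross2(a, b, cc)
      if (cr < -1e-9 * scale2) next          # reflex vertex
      if (abs(cr) <= 1e-9 * scale2) {        # collinear: drop the vertex
        idx <- idx[-j]; clipped <- TRUE; break
      }
      others <- setdiff(idx, c(ip, iv, inx))
      if (length(others)) {
        px <- ring[others, 1L]; py <- ring[others, 2L]
        d1 <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
        d2 <- (cc[1L] - b[1L]) * (py - b[2L]) - (cc[2L] - b[2L]) * (px - b[1L])
        d3 <- (a[1L] - cc[1L]) * (py - cc[2L]) - (a[2L] - cc[2L]) * (px - cc[1L])
        tol <- 1e-9 * scale2
        if (any(d1 > -tol & d2 > -tol & d3 > -tol)) next  # vertex inside ear
      }
      tris[[length(tris) + 1L]] <- rbind(a, b, cc)
      idx <- idx[-j]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L)
        stop("triangulation failed: ring is not a simple polygon")
      # last resort: perturb tolerance by dropping the most collinear vertex
      idx <- idx[-1L]
    }
  }
  if (length(idx) == 3L) {
    tri <- ring[idx, , drop = FALSE]
    if (abs(signedRingArea(tri)) > .geom_tol)
      tris[[length(tris) + 1L]] <- tri
  }
  tris
}

# Signed convex pieces of a region: outers triangulated with weight +1,
# holes with weight -1. The region indicator equals the signed sum of the
# piece indicators almost everywhere.
signedPieces <- function(region) {
  region <- asRegion(region)
  pieces <- list()
  for (p in region) {
    for (t in triangulateRing(p$outer))
      pieces[[length(pieces) + 1L]] <- list(ring = t, sign = 1)
    for (h in p$holes)
      for (t in triangulateRing(h))
        pieces[[length(pieces) + 1L]] <- list(ring = t, sign = -1)
  }
  pieces
}

#' Exact intersection area of regions
#'
#' Computes the area of the common intersection of two or more regions (or
#' bare rings) by signed convex decomposition and successive convex clipping.
#'
#' @param ... regions (lists of polygons), single polygons, or ring matrices.
#' @return Intersection area in square micrometers.
#' @export
intersectionArea <- function(...) {
  geoms <- list(...)
  geoms <- geoms[!vapply(geoms, is.null, TRUE)]
  if (length(geoms) == 0L) return(0)
  piece_sets <- lapply(geoms, signedPieces)
  if (any(vapply(piece_sets, length, 0L) == 0L)) return(0)
  # running list of signed convex cells
  cells <- lapply(piece_sets[[1L]], function(p) p)
  for (ps in piece_sets[-1L]) {
    nxt <- list()
    for (cell in cells) {
      for (p in ps) {
        r <- clipConvex(cell$ring, p$ring)
        if (nrow(r) >= 3L) {
          a <- abs(signedRingArea(r))
          if (a > .geom_tol)
            nxt[[length(nxt) + 1L]] <- list(ring = r, sign = cell$sign * p$sign)
        }
      }
    }
    cells <- nxt
    if (length(cells) == 0L) return(0)
  }
  max(0, sum(vapply(cells, function(c) c$sign * abs(signedRingArea(c$ring)), 0)))
}

#' Point-in-region test
#'
#' Membership in a region with the closed-region convention: points on an
#' outer (or hole) boundary count as inside the region.
#'
#' @param x,y point coordinates in micrometers.
#' @param region a region; an empty region contains no points.
#' @return Logical vector, one entry per point.
#' @export
pointsInRegion <- function(x, y, region) {
  region <- asRegion(region)
  res <- rep(FALSE, length(x))
  if (length(x) == 0L || length(region) == 0L) return(res)
  for (p in region) {
    ins <- pracma::inpolygon(x, y, p$outer[, 1L], p$outer[, 2L],
                             boundary = TRUE)
    if (length(p$holes)) {
      for (h in p$holes) {
        # strict interior of a hole is excluded; hole boundary stays inside
        strict <- pracma::inpolygon(x, y, h[, 1L], h[, 2L], boundary = FALSE)
        ins <- ins & !strict
      }
    }
    res <- res | ins
  }
  res
}

boundingBox <- function(region) {
  region <- asRegion(region)
  xs <- unlist(lapply(region, function(p) p$outer[, 1L]))
  ys <- unlist(lapply(region, function(p) p$outer[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
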