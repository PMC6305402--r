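# Synthetic slide generation.
#
# Verification slides: square tissue of 1 mm edge length without tumor
# compartment, holding 1,000 Ki67 objects and 50 proliferating CD8 objects
# placed uniformly at random subject to hard distance constraints. In group A
# every Ki67-CD8 distance exceeds 15 um; in group B that constraint holds for
# 45 CD8 objects while 5 CD8 objects are placed within 15 um of 5 distinct
# Ki67 objects. A minimum pairwise distance of 10 um between all objects is
# enforced in both groups. Hence the fraction of Ki67 objects within 15 um of
# the closest proliferating CD8 is exactly 0 on every A slide and at least
# 5/1000 on every B slide, making the feature perfectly discriminatory.
#
# Placement uses rejection sampling with a per-object retry budget; every
# generated slide is certified by an independent O(n^2) constraint checker
# before it is returned.

.minDist2 <- function(px, py, xs, ys) {
  if (length(xs) == 0L) return(Inf)
  min((xs - px)^2 + (ys - py)^2)
}

.placeUniform <- function(n, edge, minPairwise, avoid = NULL, rng = NULL,
                          maxTries = 10000L, label = "object") {
  xs <- numeric(0); ys <- numeric(0)
  md2 <- minPairwise^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      px <- stats::runif(1, 0, edge); py <- stats::runif(1, 0, edge)
      if (.minDist2(px, py, xs, ys) < md2) next
      if (!is.null(avoid) &&
          .minDist2(px, py, avoid$x, avoid$y) <= avoid$dist^2) next
      xs <- c(xs, px); ys <- c(ys, py); ok <- TRUE; break
    }
    if (!ok)
      stop("rejection budget exhausted while placing ", label, " ", i,
           " (min pairwise ", minPairwise, " um",
           if (!is.null(avoid)) paste0(", avoidance > ", avoid$dist, " um"),
           ")")
  }
  cbind(x = xs, y = ys)
}

#' Generate one verification slide
#'
#' @param group \code{"A"} (all CD8 farther than \code{violationRadius} from
#'   every Ki67) or \code{"B"} (\code{nViolators} CD8 objects placed within
#'   \code{violationRadius} of distinct Ki67 objects, the rest as in A).
#' @param seed RNG seed; the same (config, seed) yields bit-identical output.
#' @param tissueEdge square tissue edge length in micrometers.
#' @param nKi67,nCD8 object counts (CD8 objects are proliferating).
#' @param minPairwise minimum distance between any two objects, micrometers.
#' @param nViolators group-B count of CD8 objects violating the separation.
#' @param violationRadius Ki67-CD8 separation threshold in micrometers.
#' @param maxTries per-object rejection budget.
#' @param slideId slide identifier.
#' @return A certified [SlideObjects-class] without tumor compartment.
#' @export
generateVerificationSlide <- function(group = c("A", "B"), seed = 1,
                                      tissueEdge = 1000, nKi67 = 1000,
                                      nCD8 = 50, minPairwise = 10,
                                      nViolators = 5, violationRadius = 15,
                                      maxTries = 10000L,
                                      slideId = paste0("slide_", group, "_", seed)) {
  group <- match.arg(group)
  stopifnot(nKi67 >= 0, nCD8 >= 0, minPairwise < tissueEdge,
            nViolators <= nCD8, minPairwise < violationRadius)
  set.seed(as.integer(seed))
  ki <- .placeUniform(nKi67, tissueEdge, minPairwise, label = "Ki67")
  nFar <- if (group == "A") nCD8 else nCD8 - nViolators
  avoid <- list(x = ki[, 1L], y = ki[, 2L], dist = violationRadius)
  cd8 <- .placeUniform(nFar, tissueEdge, minPairwise, avoid = avoid,
                       label = "CD8")
  allx <- c(ki[, 1L], cd8[, 1L]); ally <- c(ki[, 2L], cd8[, 2L])
  if (group == "B" && nViolators > 0L) {
    anchors <- sample.int(nKi67, nViolators)
    md2 <- minPairwise^2
    for (a in anchors) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        r <- stats::runif(1, minPairwise, violationRadius)
        phi <- stats::runif(1, 0, 2 * pi)
        px <- ki[a, 1L] + r * cos(phi); py <- ki[a, 2L] + r * sin(phi)
        if (px < 0 || px > tissueEdge || py < 0 || py > tissueEdge) next
        if (.minDist2(px, py, allx, ally) < md2) next
        allx <- c(allx, px); ally <- c(ally, py); ok <- TRUE; break
      }
      if (!ok)
        stop("rejection budget exhausted while placing violator CD8 near ",
             "Ki67 ", a)
    }
  }
  nTot <- length(allx)
  objects <- data.frame(
    x = allx, y = ally,
    marker = c(rep("Ki67", nKi67), rep("CD8", nTot - nKi67)),
    proliferating = TRUE, stringsAsFactors = FALSE)
  slide <- makeSlide(objects,
                     tissue = rectRing(0, 0, tissueEdge, tissueEdge),
                     slideId = slideId)
  cert <- certifySlide(slide, group = group, minPairwise = minPairwise,
                       violationRadius = violationRadius,
                       nViolators = nViolators)
  if (!isTRUE(cert))
    stop("generated slide failed certification: ", cert)
  slide
}

#' Certify the distance constraints of a verification slide
#'
#' Independent O(n^2) check of the generator's constraints: all pairwise
#' object distances are at least \code{minPairwise}; in group A every
#' Ki67-CD8 distance exceeds \code{violationRadius}; in group B exactly
#' \code{nViolators} CD8 objects lie within \code{violationRadius} of a Ki67
#' object.
#'
#' @param slide a [SlideObjects-class].
#' @inheritParams generateVerificationSlide
#' @return \code{TRUE}, or a character message naming the violated
#'   constraint.
#' @export
certifySlide <- function(slide, group, minPairwise = 10,
                         violationRadius = 15, nViolators = 5) {
  o <- cellData(slide)
  d <- as.matrix(stats::dist(o[, c("x", "y")]))
  diag(d) <- Inf
  if (any(d < minPairwise - 1e-9))
    return(sprintf("pairwise distance below %g um", minPairwise))
  ki <- o$marker == "Ki67"
  cd8 <- o$marker == "CD8"
  if (!any(ki) || !any(cd8)) return(TRUE)
  nnKi <- apply(d[cd8, ki, drop = FALSE], 1L, min)
  nClose <- sum(nnKi <= violationRadius)
  if (group == "A" && nClose > 0L)
    return(sprintf("%d CD8 objects within %g um of a Ki67 in group A",
                   nClose, violationRadius))
  if (group == "B" && nClose != nViolators)
    return(sprintf("%d CD8 objects within %g um of a Ki67 in group B (want %d)",
                   nClose, violationRadius, nViolators))
  TRUE
}

#' Generate a verification cohort
#'
#' \code{nPerGroup} group-A slides (label \code{"A"}) and as many group-B
#' slides (label \code{"B"}), with per-slide seeds derived from \code{seed}.
#'
#' @param nPerGroup slides per group.
#' @param seed base seed.
#' @param ... further arguments passed to [generateVerificationSlide()].
#' @return list with \code{slides} (named list of [SlideObjects-class]) and
#'   \code{labels} (data.frame \code{slide_id}, \code{label}).
#' @export
generateVerificationCohort <- function(nPerGroup = 10, seed = 1, ...) {
  stopifnot(nPerGroup >= 1)
  base <- as.integer(seed) %% 10000L
  slides <- list()
  labels <- data.frame(slide_id = character(0), label = character(0))
  for (g in c("A", "B")) {
    for (i in seq_len(nPerGroup)) {
      s <- (base * 1000L + ifelse(g == "A", 0L, 500L) + i) %% 2147483647L
      id <- sprintf("%s%02d", g, i)
      slides[[id]] <- generateVerificationSlide(g, seed = s, slideId = id, ...)
      labels <- rbind(labels, data.frame(slide_id = id, label = g))
    }
  }
  list(slides = slides, labels = labels)
}

.discRing <- function(cx, cy, r, n = 64L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ring(cx + r * cos(a), cy + r * sin(a))
}

#' Generate a generic synthetic slide
#'
#' Homogeneous-Poisson placement per compartment with optional circular
#' hotspots that multiply the local intensity, for exercising the density,
#' distance, and heterogeneity machinery on tumor-bearing slides without
#' external data. Counts are Poisson with mean intensity x compartment area;
#' hotspot surplus points are added with mean
#' intensity x (multiplier - 1) x hotspot-compartment overlap area.
#'
#' @param tissueEdge square tissue edge length in micrometers.
#' @param tumor optional tumor region (ring/polygon/region) inside the
#'   tissue; \code{NULL} for no tumor compartment.
#' @param intensities named list: for each marker type of
#'   \code{"Ki67_prolif"}, \code{"CD4_prolif"}, \code{"CD4_nonprolif"},
#'   \code{"CD8_prolif"}, \code{"CD8_nonprolif"} either one intensity
#'   (1/mm^2, applied everywhere) or c(tumor = , non_tumor = ).
#' @param hotspots list of hotspots, each
#'   \code{list(x =, y =, radius =, multiplier =, types = )} (types optional:
#'   defaults to all).
#' @param seed RNG seed.
#' @param slideId slide identifier.
#' @return A [SlideObjects-class].
#' @export
generateGenericSlide <- function(tissueEdge = 2000, tumor = NULL,
                                 intensities = list(Ki67_prolif = 500,
                                                    CD8_prolif = 50,
                                                    CD8_nonprolif = 100,
                                                    CD4_prolif = 30,
                                                    CD4_nonprolif = 80),
                                 hotspots = list(), seed = 1,
                                 slideId = "generic") {
  set.seed(as.integer(seed))
  tissue <- polygonRegion(rectRing(0, 0, tissueEdge, tissueEdge))
  tumor <- asRegion(tumor)
  regions <- list(tissue = tissue, tumor = tumor, exclusions = list())
  areas <- compartmentAreasUm2(regions) / 1e6
  comps <- if (length(tumor)) c("tumor", "non_tumor") else "non_tumor"
  sampleIn <- function(n, comp) {
    # rejection from the tissue bounding box into the compartment
    out <- matrix(numeric(0), 0L, 2L)
    while (nrow(out) < n) {
      m <- max(32L, 2L * (n - nrow(out)))
      px <- stats::runif(m, 0, tissueEdge); py <- stats::runif(m, 0, tissueEdge)
      keep <- compartmentOf(px, py, regions) == comp
      out <- rbind(out, cbind(px[keep], py[keep]))
    }
    out[seq_len(n), , drop = FALSE]
  }
  rows <- list()
  for (type in names(intensities)) {
    parts <- strsplit(type, "_", fixed = TRUE)[[1L]]
    marker <- parts[1L]; prolif <- parts[2L] == "prolif"
    lam <- intensities[[type]]
    for (comp in comps) {
      l <- if (length(lam) > 1L) lam[[comp]] else lam[[1L]]
      stopifnot(l >= 0)
      a <- areas[[if (comp == "tumor") "tumor" else "non_tumor"]]
      if (a <= 0 || l == 0) next
      n <- stats::rpois(1L, l * a)
      if (n > 0L) {
        xy <- sampleIn(n, comp)
        rows[[length(rows) + 1L]] <- data.frame(
          x = xy[, 1L], y = xy[, 2L], marker = marker,
          proliferating = prolif, stringsAsFactors = FALSE)
      }
      for (h in hotspots) {
        if (!is.null(h$types) && !type %in% h$types) next
        disc <- polygonRegion(.discRing(h$x, h$y, h$radius))
        ov <- intersectionArea(tissue, disc)
        if (length(tumor)) {
          tv <- intersectionArea(tissue, tumor, disc)
          ov <- if (comp == "tumor") tv else ov - tv
        }
        lamExtra <- l * (h$multiplier - 1) * ov / 1e6
        if (lamExtra <= 0) next
        nh <- stats::rpois(1L, lamExtra)
        got <- matrix(numeric(0), 0L, 2L)
        while (nrow(got) < nh) {
          m <- max(32L, 2L * (nh - nrow(got)))
          r <- h$radius * sqrt(stats::runif(m))
          phi <- stats::runif(m, 0, 2 * pi)
          px <- h$x + r * cos(phi); py <- h$y + r * sin(phi)
          keep <- compartmentOf(px, py, regions) == comp
          got <- rbind(got, cbind(px[keep], py[keep]))
        }
        if (nh > 0L) {
          got <- got[seq_len(nh), , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            x = got[, 1L], y = got[, 2L], marker = marker,
            proliferating = prolif, stringsAsFactors = FALSE)
        }
      }
    }
  }
  objects <- if (length(rows)) do.call(rbind, rows)
  else data.frame(x = numeric(0), y = numeric(0), marker = character(0),
                  proliferating = logical(0), stringsAsFactors = FALSE)
  makeSlide(objects, tissue = tissue, tumor = tumor, slideId = slideId)
}

#' Write a cohort in the slide file formats
#'
#' Emits per-slide GeoJSON region files and object CSVs plus a labels CSV, so
#' generated cohorts are indistinguishable from real inputs downstream.
#'
#' @param cohort list with \code{slides} and \code{labels}, as returned by
#'   [generateVerificationCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$slides)) {
    writeRegionsGeoJSON(cohort$slides[[id]],
                        file.path(dir, paste0(id, "_regions.geojson")))
    writeObjectsCSV(cohort$slides[[id]],
                    file.path(dir, paste0(id, "_objects.csv")))
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#' @param dir directory with per-slide \code{*_regions.geojson} /
#'   \code{*_objects.csv} pairs and a \code{labels.csv}.
#' @return list with \code{slides} and \code{labels}.
#' @export
readCohort <- function(dir) {
  regs <- sort(list.files(dir, pattern = "_regions\\.geojson$",
                          full.names = TRUE))
  slides <- list()
  for (rf in regs) {
    id <- sub("_regions\\.geojson$", "", basename(rf))
    of <- file.path(dir, paste0(id, "_objects.csv"))
    if (!file.exists(of)) stop("missing objects file for slide ", id)
    slides[[id]] <- loadSlide(rf, of, slideId = id)
  }
  labels <- readLabels(file.path(dir, "labels.csv"))
  list(slides = slides, labels = labels)
}
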