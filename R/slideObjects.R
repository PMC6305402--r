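# Slide model: typed 2D cell point sets with tissue/tumor/exclusion regions.

#' SlideObjects: annotated cell point data for one slide
#'
#' Holds the cell objects of one slide (coordinates in micrometers, marker
#' type, proliferation state), the region geometry (entire tissue, tumor
#' annotation, exclusion polygons), the derived compartment of every retained
#' object, and the compartment areas in square millimeters. Objects outside
#' the tissue or inside an exclusion polygon are dropped at construction and
#' counted in the \code{log} slot.
#'
#' Compartments: \emph{tumor} is the intersection of the tissue with the
#' tumor annotation; \emph{non_tumor} is the tissue without the tumor
#' annotation; both exclude the exclusion polygons. Boundary points count as
#' inside (closed regions) and the tumor takes precedence on a shared
#' boundary, so every retained object lies in exactly one compartment.
#'
#' @slot slideId character slide identifier.
#' @slot objects data.frame with columns \code{x}, \code{y} (micrometers),
#'   \code{marker} (Ki67/CD4/CD8), \code{proliferating} (logical),
#'   \code{compartment} (factor: tumor/non_tumor).
#' @slot regions list with elements \code{tissue}, \code{tumor},
#'   \code{exclusions}, each a region (list of polygons).
#' @slot areas named numeric: \code{entire}, \code{tumor}, \code{non_tumor}
#'   areas in square millimeters.
#' @slot log list of load/filter counters.
#' @export
setClass("SlideObjects",
  representation(slideId = "character", objects = "data.frame",
                 regions = "list", areas = "numeric", log = "list"))

setValidity("SlideObjects", function(object) {
  msgs <- character(0)
  req <- c("x", "y", "marker", "proliferating", "compartment")
  if (!all(req %in% names(object@objects)))
    msgs <- c(msgs, "objects must have columns x, y, marker, proliferating, compartment")
  else {
    if (any(!is.finite(object@objects$x)) || any(!is.finite(object@objects$y)))
      msgs <- c(msgs, "coordinates must be finite")
    if (!all(object@objects$marker %in% .markers))
      msgs <- c(msgs, "marker must be one of Ki67, CD4, CD8")
    bad <- object@objects$marker == "Ki67" & !object@objects$proliferating
    if (any(bad))
      msgs <- c(msgs, "Ki67 single-positive objects are proliferating by definition")
  }
  if (!all(c("entire", "tumor", "non_tumor") %in% names(object@areas)))
    msgs <- c(msgs, "areas must be named entire, tumor, non_tumor")
  else {
    if (any(object@areas < -1e-9))
      msgs <- c(msgs, "areas must be non-negative")
    if (abs(object@areas[["tumor"]] + object@areas[["non_tumor"]] -
            object@areas[["entire"]]) > 1e-6)
      msgs <- c(msgs, "tumor + non_tumor area must equal entire-tissue area")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SlideObjects slide identifier
#' @param object,x a \code{SlideObjects}.
#' @export
setGeneric("slideId", function(object) standardGeneric("slideId"))
#' @describeIn SlideObjects slide identifier
#' @export
setMethod("slideId", "SlideObjects", function(object) object@slideId)

#' @describeIn SlideObjects retained cell objects (with compartment column)
#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))
#' @describeIn SlideObjects retained cell objects
#' @export
setMethod("cellData", "SlideObjects", function(object) object@objects)

#' @describeIn SlideObjects region geometry list (tissue, tumor, exclusions)
#' @export
setGeneric("slideRegions", function(object) standardGeneric("slideRegions"))
#' @describeIn SlideObjects region geometry
#' @export
setMethod("slideRegions", "SlideObjects", function(object) object@regions)

#' @describeIn SlideObjects compartment areas in square millimeters
#' @export
setGeneric("regionAreas", function(object) standardGeneric("regionAreas"))
#' @describeIn SlideObjects compartment areas
#' @export
setMethod("regionAreas", "SlideObjects", function(object) object@areas)

setMethod("show", "SlideObjects", function(object) {
  cat("SlideObjects '", object@slideId, "'\n", sep = "")
  cat(sprintf("  %d objects (%s)\n", nrow(object@objects),
              paste(sprintf("%s: %d", names(table(object@objects$marker)),
                            as.integer(table(object@objects$marker))),
                    collapse = ", ")))
  cat(sprintf("  areas [mm^2]: entire %.4f, tumor %.4f, non-tumor %.4f\n",
              object@areas[["entire"]], object@areas[["tumor"]],
              object@areas[["non_tumor"]]))
  if (length(object@log))
    cat(sprintf("  dropped: %d outside tissue, %d in exclusions\n",
                object@log$n_outside %||% 0L, object@log$n_excluded %||% 0L))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compartment of points
#'
#' Assigns each point to the tumor or non-tumor compartment of the tissue, or
#' to \code{outside}. Points on a region boundary count as inside; the tumor
#' compartment takes precedence over non-tumor on the shared boundary, and
#' points inside (or on the boundary of) an exclusion polygon are
#' \code{outside}.
#'
#' @param x,y point coordinates in micrometers.
#' @param regions list with \code{tissue}, \code{tumor}, \code{exclusions}
#'   regions, as in [slideRegions()].
#' @return factor with levels tumor, non_tumor, outside.
#' @export
compartmentOf <- function(x, y, regions) {
  inTissue <- pointsInRegion(x, y, regions$tissue)
  if (length(asRegion(regions$exclusions)))
    inTissue <- inTissue & !pointsInRegion(x, y, regions$exclusions)
  inTumor <- if (length(asRegion(regions$tumor)))
    pointsInRegion(x, y, regions$tumor) else rep(FALSE, length(x))
  out <- ifelse(!inTissue, "outside", ifelse(inTumor, "tumor", "non_tumor"))
  factor(out, levels = c("tumor", "non_tumor", "outside"))
}

compartmentAreasUm2 <- function(regions) {
  tissue <- asRegion(regions$tissue)
  tumor <- asRegion(regions$tumor)
  excl <- asRegion(regions$exclusions)
  entire <- regionArea(tissue)
  if (length(excl)) entire <- entire - intersectionArea(tissue, excl)
  tum <- 0
  if (length(tumor)) {
    tum <- intersectionArea(tissue, tumor)
    if (length(excl)) tum <- tum - intersectionArea(tissue, tumor, excl)
  }
  entire <- max(0, entire); tum <- min(max(0, tum), entire)
  c(entire = entire, tumor = tum, non_tumor = entire - tum)
}

#' Build a SlideObjects from raw components
#'
#' Derives compartments and areas, drops objects outside the tissue or in
#' exclusion polygons, and validates invariants.
#'
#' @param objects data.frame with columns \code{x}, \code{y},
#'   \code{marker}, \code{proliferating}.
#' @param tissue tissue region (ring matrix, polygon, or region); required.
#' @param tumor,exclusions optional regions.
#' @param slideId slide identifier.
#' @return A [SlideObjects-class] object.
#' @export
makeSlide <- function(objects, tissue, tumor = NULL, exclusions = NULL,
                      slideId = "slide") {
  if (is.null(tissue) || length(asRegion(tissue)) == 0L)
    stop("a tissue region is required")
  regions <- list(tissue = asRegion(tissue), tumor = asRegion(tumor),
                  exclusions = asRegion(exclusions))
  objects$marker <- as.character(objects$marker)
  objects$proliferating <- as.logical(objects$proliferating)
  comp <- compartmentOf(objects$x, objects$y, regions)
  inTiss <- pointsInRegion(objects$x, objects$y, regions$tissue)
  n_outside <- sum(!inTiss)
  n_excluded <- sum(inTiss & comp == "outside")
  keep <- comp != "outside"
  objects <- objects[keep, c("x", "y", "marker", "proliferating"), drop = FALSE]
  objects$compartment <- droplevels(comp[keep], exclude = "outside")
  objects$compartment <- factor(as.character(objects$compartment),
                                levels = c("tumor", "non_tumor"))
  rownames(objects) <- NULL
  areas <- compartmentAreasUm2(regions) / 1e6  # um^2 -> mm^2
  methods::new("SlideObjects", slideId = as.character(slideId),
               objects = objects, regions = regions, areas = areas,
               log = list(n_outside = n_outside, n_excluded = n_excluded,
                          n_retained = nrow(objects)))
}
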