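# Slide file I/O.
#
# Regions are GeoJSON FeatureCollections (coordinates in micrometers); each
# Feature is a Polygon or MultiPolygon with property "role" in
# {tissue, tumor, exclude}. Objects are CSV with header
# slide_id,x_um,y_um,marker,proliferating; labels are CSV slide_id,label.

.ringFromCoords <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt)
    c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]]))))
  normalizeRing(m)
}

.polysFromGeometry <- function(geom) {
  type <- geom$type
  if (identical(type, "Polygon")) {
    rings <- lapply(geom$coordinates, .ringFromCoords)
    list(list(outer = rings[[1L]], holes = rings[-1L]))
  } else if (identical(type, "MultiPolygon")) {
    lapply(geom$coordinates, function(poly) {
      rings <- lapply(poly, .ringFromCoords)
      list(outer = rings[[1L]], holes = rings[-1L])
    })
  } else {
    stop("unsupported geometry type: ", type)
  }
}

#' Read region annotations from GeoJSON
#'
#' @param path GeoJSON FeatureCollection; every Feature must carry a
#'   property \code{role} in tissue / tumor / exclude. Coordinates are
#'   micrometers.
#' @return list with regions \code{tissue}, \code{tumor}, \code{exclusions}.
#' @export
readRegionsGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("region file must be a GeoJSON FeatureCollection")
  regions <- list(tissue = list(), tumor = list(), exclusions = list())
  for (f in gj$features) {
    role <- f$properties$role
    if (is.null(role) || !role %in% c("tissue", "tumor", "exclude"))
      stop("every region feature needs a role in {tissue, tumor, exclude}")
    key <- switch(role, tissue = "tissue", tumor = "tumor",
                  exclude = "exclusions")
    regions[[key]] <- c(regions[[key]], .polysFromGeometry(f$geometry))
  }
  if (length(regions$tissue) == 0L)
    stop("region file contains no polygon with role 'tissue'")
  regions
}

.regionToFeatures <- function(region, role) {
  lapply(asRegion(region), function(p) {
    coords <- c(list(lapply(seq_len(nrow(p$outer)), function(i)
                  as.numeric(p$outer[i, ]))),
                lapply(p$holes, function(h)
                  lapply(seq_len(nrow(h)), function(i) as.numeric(h[i, ]))))
    # close each ring
    coords <- lapply(coords, function(r) c(r, r[1L]))
    list(type = "Feature", properties = list(role = role),
         geometry = list(type = "Polygon", coordinates = coords))
  })
}

#' Write slide regions to GeoJSON
#' @param slide a [SlideObjects-class].
#' @param path output file.
#' @export
writeRegionsGeoJSON <- function(slide, path) {
  r <- slideRegions(slide)
  feats <- c(.regionToFeatures(r$tissue, "tissue"),
             .regionToFeatures(r$tumor, "tumor"),
             .regionToFeatures(r$exclusions, "exclude"))
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write slide objects to CSV
#' @param slide a [SlideObjects-class].
#' @param path output file.
#' @export
writeObjectsCSV <- function(slide, path) {
  o <- cellData(slide)
  utils::write.csv(
    data.frame(slide_id = slideId(slide), x_um = o$x, y_um = o$y,
               marker = o$marker,
               proliferating = as.integer(o$proliferating)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readObjectsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("slide_id", "x_um", "y_um", "marker", "proliferating")
  if (!all(req %in% names(df)))
    stop("objects file must have columns ", paste(req, collapse = ", "))
  bad <- which(!df$marker %in% .markers |
               !df$proliferating %in% c(0, 1) |
               !is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("malformed object rows (1-based, excluding header): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(df$marker == "Ki67" & df$proliferating != 1)
  if (length(bad))
    stop("Ki67 rows must have proliferating=1; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  df
}

#' Load a slide from region and object files
#'
#' Reads the GeoJSON region annotations and the object CSV, derives the
#' tumor/non-tumor compartments, drops objects outside the tissue or inside
#' exclusion polygons (counted in the slide log), and returns the assembled
#' slide. When no tumor polygon is annotated the tumor region is empty and
#' the whole tissue is the non-tumor compartment; tumor-region features are
#' later reported unavailable.
#'
#' @param regionFile GeoJSON path (see [readRegionsGeoJSON()]).
#' @param objectsFile CSV path with header
#'   \code{slide_id,x_um,y_um,marker,proliferating}.
#' @param slideId optional; defaults to the (unique) slide_id in the CSV.
#' @return A [SlideObjects-class].
#' @export
loadSlide <- function(regionFile, objectsFile, slideId = NULL) {
  regions <- readRegionsGeoJSON(regionFile)
  df <- .readObjectsCSV(objectsFile)
  if (is.null(slideId)) {
    ids <- unique(df$slide_id)
    if (length(ids) > 1L)
      stop("objects file contains multiple slide_ids; pass slideId")
    slideId <- if (length(ids)) ids else "slide"
  } else {
    df <- df[df$slide_id == slideId, , drop = FALSE]
  }
  makeSlide(
    data.frame(x = df$x_um, y = df$y_um, marker = df$marker,
               proliferating = as.logical(df$proliferating)),
    tissue = regions$tissue, tumor = regions$tumor,
    exclusions = regions$exclusions, slideId = slideId)
}

#' Read a cohort label table
#' @param path CSV with header \code{slide_id,label}; exactly two distinct
#'   labels are required for ranking.
#' @return data.frame slide_id, label.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("slide_id", "label") %in% names(df)))
    stop("labels file must have columns slide_id,label")
  if (anyDuplicated(df$slide_id))
    stop("every slide must have exactly one label")
  df
}
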