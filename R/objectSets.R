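# Cell object-set catalog.
#
# Atomic markers are Ki67 (single-positive, by definition proliferating
# non-T cells), CD4 and CD8, the latter two split into proliferating and
# non-proliferating subsets. An object set is a named predicate over
# (marker, proliferating); sets may be unions of atomic sets.

.markers <- c("Ki67", "CD4", "CD8")

# A set definition is list(markers = character, prolif = NA/TRUE/FALSE):
# membership = marker %in% markers & (is.na(prolif) | proliferating == prolif)
.setDef <- function(markers, prolif = NA) list(markers = markers, prolif = prolif)

#' Default object-set catalog
#'
#' The 10 default object sets: Ki67 single-positives, the CD4 and CD8 sets
#' (any / proliferating / non-proliferating), and the combined T-cell sets
#' (CD4 or CD8, in the same three variants).
#'
#' @param extended if \code{TRUE}, append three union sets (all cells, all
#'   proliferating cells, all non-proliferating cells) used when enumerating
#'   ratio pairs, giving 13 sets in total.
#' @return Named list of set definitions usable with [setMembership()].
#' @examples
#' names(objectSetCatalog())
#' @export
objectSetCatalog <- function(extended = FALSE) {
  cat <- list(
    Ki67          = .setDef("Ki67"),
    CD4_any       = .setDef("CD4"),
    CD4_prolif    = .setDef("CD4", TRUE),
    CD4_nonprolif = .setDef("CD4", FALSE),
    CD8_any       = .setDef("CD8"),
    CD8_prolif    = .setDef("CD8", TRUE),
    CD8_nonprolif = .setDef("CD8", FALSE),
    Tcell_any       = .setDef(c("CD4", "CD8")),
    Tcell_prolif    = .setDef(c("CD4", "CD8"), TRUE),
    Tcell_nonprolif = .setDef(c("CD4", "CD8"), FALSE)
  )
  if (extended) {
    cat <- c(cat, list(
      all_cells     = .setDef(.markers),
      all_prolif    = .setDef(.markers, TRUE),
      all_nonprolif = .setDef(c("CD4", "CD8"), FALSE)
    ))
  }
  cat
}

#' Object-set membership
#'
#' @param objects data.frame with columns \code{marker} and
#'   \code{proliferating} (logical or 0/1).
#' @param set a set definition from [objectSetCatalog()] or a set name.
#' @param catalog catalog to resolve names against.
#' @return Logical membership vector.
#' @export
setMembership <- function(objects, set, catalog = objectSetCatalog(TRUE)) {
  if (is.character(set)) {
    if (!set %in% names(catalog))
      stop("unknown object set: ", set)
    set <- catalog[[set]]
  }
  m <- objects$marker %in% set$markers
  if (!is.na(set$prolif))
    m <- m & (as.logical(objects$proliferating) == set$prolif)
  m
}

# n x k logical membership matrix over named sets
membershipMatrix <- function(objects, setNames,
                             catalog = objectSetCatalog(TRUE)) {
  m <- vapply(setNames,
              function(s) setMembership(objects, s, catalog),
              logical(nrow(objects)))
  if (nrow(objects) == 1L) m <- matrix(m, nrow = 1L,
                                       dimnames = list(NULL, setNames))
  if (nrow(objects) == 0L) m <- matrix(FALSE, 0L, length(setNames),
                                       dimnames = list(NULL, setNames))
  colnames(m) <- setNames
  m
}
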