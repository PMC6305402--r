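# Feature ranking by discriminatory power.
#
# Discrimination of a single feature between two slide classes is quantified
# by the Mann-Whitney ROC-AUC (ties counted 1/2), folded into [0.5, 1] by
# replacing values below 0.5 with their mirror 1 - AUC. The overall
# performance measure (OPM) scales the folded AUC to [0, 1] and multiplies
# by the per-class availability fractions:
#   OPM = 2 * (foldedAUC - 0.5) * (C1f / C1) * (C2f / C2),
# where C1, C2 are the class sizes and C1f, C2f the numbers of slides per
# class on which the feature is available.

#' Folded ROC-AUC of one feature
#'
#' Mann-Whitney AUC with ties counted one half, computed on the available
#' (non-NA) values, folded into [0.5, 1]: an AUC below 0.5 is replaced by
#' 1 - AUC since both separation directions are equally useful.
#'
#' @param values1,values2 feature values of the two classes (NA =
#'   unavailable).
#' @return folded AUC in [0.5, 1], or \code{NA} when either class has no
#'   available value (unrankable feature).
#' @export
foldedAUC <- function(values1, values2) {
  v1 <- values1[!is.na(values1)]
  v2 <- values2[!is.na(values2)]
  n1 <- length(v1); n2 <- length(v2)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(v1, v2))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  max(auc, 1 - auc)
}

#' Overall performance measure (OPM)
#'
#' @param foldedAuc folded ROC-AUC in [0.5, 1]; \code{NA} (unrankable) maps
#'   to OPM 0.
#' @param C1,C2 total slide counts of the two classes (both > 0).
#' @param C1f,C2f per-class counts of slides on which the feature is
#'   available.
#' @return OPM in [0, 1].
#' @export
opm <- function(foldedAuc, C1, C2, C1f = C1, C2f = C2) {
  if (C1 <= 0 || C2 <= 0)
    stop("both classes must contain at least one slide")
  stopifnot(C1f >= 0, C1f <= C1, C2f >= 0, C2f <= C2)
  if (is.na(foldedAuc)) return(0)
  2 * (foldedAuc - 0.5) * (C1f / C1) * (C2f / C2)
}

#' Assemble a feature matrix
#'
#' Combines per-slide feature values into a \code{SummarizedExperiment}:
#' assay \code{values} (numeric; NA = unavailable), assay \code{reason}
#' (unavailability reason codes: 0 none, 1 region_missing, 2 nonfinite),
#' feature metadata as \code{rowData}, and the class labels as
#' \code{colData$label}.
#'
#' @param results named list (by slide id) of data.frames
#'   \code{feature_id}, \code{value}, \code{reason} over an identical
#'   catalog.
#' @param labels data.frame \code{slide_id}, \code{label}.
#' @param rowMeta optional data.frame of feature metadata with a
#'   \code{feature_id} column (e.g. the catalog).
#' @return A \code{SummarizedExperiment} (features x slides).
#' @export
buildFeatureMatrix <- function(results, labels = NULL, rowMeta = NULL) {
  stopifnot(length(results) >= 1L)
  ids <- results[[1L]]$feature_id
  for (r in results)
    if (!identical(r$feature_id, ids))
      stop("all slides must be computed over the identical catalog")
  values <- vapply(results, `[[`, numeric(length(ids)), "value")
  reasonCode <- c(none = 0L, region_missing = 1L, nonfinite = 2L)
  reason <- vapply(results,
                   function(r) reasonCode[r$reason], integer(length(ids)))
  if (!is.matrix(values)) {
    values <- matrix(values, nrow = length(ids))
    reason <- matrix(reason, nrow = length(ids))
  }
  dimnames(values) <- dimnames(reason) <- list(ids, names(results))
  cd <- S4Vectors::DataFrame(row.names = names(results))
  if (!is.null(labels)) {
    m <- match(names(results), labels$slide_id)
    if (anyNA(m)) stop("every analyzed slide needs a label")
    cd$label <- labels$label[m]
  }
  rd <- S4Vectors::DataFrame(feature_id = ids, row.names = ids)
  if (!is.null(rowMeta)) {
    mm <- match(ids, rowMeta$feature_id)
    if (!anyNA(mm))
      rd <- S4Vectors::DataFrame(rowMeta[mm, , drop = FALSE], row.names = ids)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values, reason = reason),
    rowData = rd, colData = cd)
}

.labelsOf <- function(se) {
  lab <- SummarizedExperiment::colData(se)$label
  if (is.null(lab)) stop("feature matrix carries no class labels")
  lv <- sort(unique(as.character(lab)))
  if (length(lv) != 2L)
    stop("exactly two classes are required for ranking")
  list(lab = as.character(lab), levels = lv)
}

# folded AUC + availability for every row of a values matrix
.rankStats <- function(values, lab, levels) {
  i1 <- lab == levels[1L]; i2 <- lab == levels[2L]
  C1 <- sum(i1); C2 <- sum(i2)
  st <- t(apply(values, 1L, function(v) {
    a <- foldedAUC(v[i1], v[i2])
    c(a, sum(!is.na(v[i1])), sum(!is.na(v[i2])))
  }))
  data.frame(folded_auc = st[, 1L], C1f = as.integer(st[, 2L]),
             C2f = as.integer(st[, 3L]),
             opm = ifelse(is.na(st[, 1L]), 0,
                          2 * (st[, 1L] - 0.5) * (st[, 2L] / C1) *
                            (st[, 3L] / C2)),
             C1 = C1, C2 = C2)
}

#' Rank features by OPM
#'
#' Computes folded ROC-AUC, per-class availability, and OPM for every
#' feature, and returns the features in descending OPM order (ties broken by
#' the canonical feature id). Features with OPM at or above the screening
#' threshold are flagged potentially predictive.
#'
#' @param se feature matrix from [buildFeatureMatrix()] with two-class
#'   labels.
#' @param opmThreshold screening threshold (default 0.6).
#' @return data.frame \code{feature_id}, \code{folded_auc}, \code{C1f},
#'   \code{C2f}, \code{opm}, \code{potentially_predictive}, plus the feature
#'   metadata columns of the matrix, ordered by descending OPM.
#' @export
rankFeatures <- function(se, opmThreshold = 0.6) {
  l <- .labelsOf(se)
  values <- SummarizedExperiment::assay(se, "values")
  st <- .rankStats(values, l$lab, l$levels)
  out <- data.frame(feature_id = rownames(values), st[, 1:4],
                    stringsAsFactors = FALSE)
  out$unrankable <- is.na(out$folded_auc)
  out$potentially_predictive <- out$opm >= opmThreshold
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  extra <- setdiff(names(rd), names(out))
  if (length(extra)) out <- cbind(out, rd[, extra, drop = FALSE])
  out <- out[order(-out$opm, out$feature_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screening summary of a ranking
#'
#' Counts of potentially predictive features, split by feature class
#' (global vs heterogeneity, density- vs distance-based) and by distance
#' threshold (including "(none)" for density-based features).
#'
#' @param ranked output of [rankFeatures()] carrying the catalog columns
#'   \code{group} and \code{theta}.
#' @return list with data.frames \code{by_class} and \code{by_threshold}.
#' @export
screeningSummary <- function(ranked) {
  if (!all(c("group", "theta") %in% names(ranked)))
    stop("ranking must carry the catalog columns 'group' and 'theta'")
  pp <- ranked[ranked$potentially_predictive, , drop = FALSE]
  isHet <- grepl("^het\\|", pp$feature_id)
  by_class <- data.frame(
    class = c("global", "heterogeneity"),
    density_based = c(sum(!isHet & pp$group == "density"),
                      sum(isHet & pp$group == "density")),
    distance_based = c(sum(!isHet & pp$group == "distance"),
                       sum(isHet & pp$group == "distance")))
  thetas <- sort(unique(ranked$theta[!is.na(ranked$theta)]))
  bucket <- ifelse(is.na(pp$theta), "(none)", as.character(pp$theta))
  lv <- c(as.character(thetas), "(none)")
  by_threshold <- data.frame(
    theta = lv,
    n_potentially_predictive = as.integer(table(factor(bucket, levels = lv))))
  list(by_class = by_class, by_threshold = by_threshold)
}

#' Null OPM distribution from pseudo-random features
#'
#' Generates a feature matrix of i.i.d. uniform(0, 1) values with the same
#' slide class assignment (full availability), computes the OPM of every
#' random feature, and summarizes the distribution. Since the ROC-AUC is
#' invariant under monotone transforms, the uniform distribution stands in
#' for any continuous null feature.
#'
#' @param nFeatures number of random features.
#' @param labels vector of class labels (length = number of slides, exactly
#'   two distinct values, both present).
#' @param seed RNG seed.
#' @param thresholds OPM thresholds at which exceedance counts are reported.
#' @param breaks histogram break points for the OPM summary.
#' @return list with \code{opm} (numeric vector), \code{exceedance} (named
#'   counts of features with OPM >= threshold), and \code{histogram}
#'   (data.frame bin_low, bin_high, count).
#' @export
significanceNull <- function(nFeatures, labels, seed = 1,
                             thresholds = 0.6,
                             breaks = seq(0, 1, by = 0.05)) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L)
    stop("labels must contain exactly two classes (both non-empty)")
  lab <- as.character(labels)
  set.seed(as.integer(seed))
  values <- matrix(stats::runif(nFeatures * length(lab)), nrow = nFeatures)
  st <- .rankStats(values, lab, lv)
  opmv <- st$opm
  h <- graphics::hist(opmv, breaks = breaks, plot = FALSE)
  list(opm = opmv,
       exceedance = stats::setNames(
         vapply(thresholds, function(t) sum(opmv >= t), 0L),
         as.character(thresholds)),
       histogram = data.frame(bin_low = h$breaks[-length(h$breaks)],
                              bin_high = h$breaks[-1L], count = h$counts))
}
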