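# End-to-end orchestration: per-slide feature computation (optionally in
# parallel, one process per slide), a per-slide plain-text feature store
# merged at the end, result-level caching keyed on (slide content hash,
# config hash), and report generation.

# deterministic content hash (md5 of the serialized text); used as cache key
.contentHash <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

configHash <- function(config) {
  .contentHash(paste(deparse(config), collapse = "\n"))
}

slideHash <- function(slide) {
  o <- cellData(slide)
  .contentHash(paste(c(sprintf("%.6f", c(o$x, o$y)), o$marker,
                       as.integer(o$proliferating),
                       sprintf("%.9f", regionAreas(slide))), collapse = ","))
}

#' Compute all features of one slide
#'
#' Global features plus heterogeneity features, one row per catalog spec.
#'
#' @param slide a [SlideObjects-class].
#' @param config an [catalogConfig()] object.
#' @param cat,hetCat optional pre-built catalogs for \code{config}.
#' @return data.frame \code{feature_id}, \code{value}, \code{reason}.
#' @export
analyzeSlide <- function(slide, config = catalogConfig(),
                         cat = featureCatalog(config),
                         hetCat = heterogeneityCatalog(config)) {
  rbind(computeGlobalFeatures(slide, config, cat),
        computeHeterogeneityFeatures(slide, config, hetCat))
}

.storePath <- function(storeDir, id) file.path(storeDir, paste0(id, ".tsv"))

.writeStore <- function(res, slide, config, storeDir) {
  path <- .storePath(storeDir, slideId(slide))
  con <- file(path, "w")
  writeLines(c(paste0("# slide_id\t", slideId(slide)),
               paste0("# slide_hash\t", slideHash(slide)),
               paste0("# config_hash\t", configHash(config)),
               paste0("# created\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             con)
  utils::write.table(res, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  path
}

.readStore <- function(storeDir, id, slide = NULL, config = NULL) {
  path <- .storePath(storeDir, id)
  if (!file.exists(path)) return(NULL)
  hdr <- readLines(path, n = 4L)
  meta <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- stats::setNames(meta[, 2L], meta[, 1L])
  if (!is.null(slide) && !identical(unname(meta[["slide_hash"]]),
                                    slideHash(slide))) return(NULL)
  if (!is.null(config) && !identical(unname(meta[["config_hash"]]),
                                     configHash(config))) return(NULL)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Analyze a cohort of slides
#'
#' Computes the full feature catalog for every slide, optionally in parallel
#' (one worker process per slide) and with a per-slide plain-text store used
#' as a result cache: a rerun with identical slide content and configuration
#' reads the stored values instead of recomputing. Per-slide failures are
#' isolated and reported; non-failing slides are retained.
#'
#' @param slides named list of [SlideObjects-class] (names = slide ids).
#' @param config an [catalogConfig()] object.
#' @param workers number of parallel workers (forked processes).
#' @param storeDir optional directory for the per-slide feature store.
#' @return named list of per-slide result data.frames; failed slides are
#'   dropped and reported in attribute \code{"failures"} (named character of
#'   error messages).
#' @export
analyzeCohort <- function(slides, config = catalogConfig(), workers = 1L,
                          storeDir = NULL) {
  if (is.null(names(slides)))
    names(slides) <- vapply(slides, slideId, "")
  if (!is.null(storeDir))
    dir.create(storeDir, showWarnings = FALSE, recursive = TRUE)
  cat <- featureCatalog(config)
  hetCat <- heterogeneityCatalog(config)
  one <- function(id) {
    tryCatch({
      slide <- slides[[id]]
      if (!is.null(storeDir)) {
        cached <- .readStore(storeDir, id, slide, config)
        if (!is.null(cached)) return(cached)
      }
      res <- analyzeSlide(slide, config, cat, hetCat)
      if (!is.null(storeDir)) .writeStore(res, slide, config, storeDir)
      res
    }, error = function(e) e)
  }
  ids <- names(slides)
  results <- if (workers > 1L)
    parallel::mclapply(ids, one, mc.cores = workers)
  else lapply(ids, one)
  names(results) <- ids
  failed <- vapply(results, inherits, TRUE, "error")
  failures <- vapply(results[failed], conditionMessage, "")
  results <- results[!failed]
  if (any(failed))
    warning(sum(failed), " slide(s) failed: ",
            paste(names(failures), collapse = ", "))
  attr(results, "failures") <- failures
  results
}

#' Merge a feature store directory into a feature matrix
#'
#' @param storeDir directory of per-slide store files written by
#'   [analyzeCohort()].
#' @param labels optional label table (data.frame \code{slide_id},
#'   \code{label}).
#' @param rowMeta optional feature metadata (e.g. the combined catalog).
#' @return A \code{SummarizedExperiment}, see [buildFeatureMatrix()].
#' @export
mergeStores <- function(storeDir, labels = NULL, rowMeta = NULL) {
  files <- sort(list.files(storeDir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no store files in ", storeDir)
  results <- lapply(files, function(f)
    utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE))
  names(results) <- sub("\\.tsv$", "", basename(files))
  buildFeatureMatrix(results, labels, rowMeta)
}

.combinedCatalog <- function(config) {
  g <- featureCatalog(config)
  h <- heterogeneityCatalog(config)
  h$region <- NA_character_
  g$measure <- NA_character_; g$edge <- NA_real_; g$scope <- NA_character_
  g$base_id <- NA_character_
  rbind(g, h[, names(g)])
}

#' Run the full discovery pipeline on a cohort
#'
#' Convenience wrapper: analyze all slides, assemble the feature matrix, rank
#' the features by OPM, and summarize the screening.
#'
#' @inheritParams analyzeCohort
#' @param labels data.frame \code{slide_id}, \code{label} with exactly two
#'   classes.
#' @return list with \code{matrix} (SummarizedExperiment), \code{ranked}
#'   (data.frame from [rankFeatures()]), \code{screening} (from
#'   [screeningSummary()]) and \code{census} (from [catalogCensus()]).
#' @export
runPipeline <- function(slides, labels, config = catalogConfig(),
                        workers = 1L, storeDir = NULL) {
  results <- analyzeCohort(slides, config, workers, storeDir)
  se <- buildFeatureMatrix(results, labels, .combinedCatalog(config))
  ranked <- rankFeatures(se, config$opmThreshold)
  list(matrix = se, ranked = ranked, screening = screeningSummary(ranked),
       census = catalogCensus(config))
}

#' Write ranking and significance reports
#'
#' Writes the ranked feature TSV, the screening summaries, and a real-vs-null
#' OPM histogram comparison.
#'
#' @param pipeline result of [runPipeline()].
#' @param outDir output directory.
#' @param nullFeatures size of the pseudo-random null feature matrix.
#' @param seed RNG seed for the null model.
#' @return invisibly, the output directory.
#' @export
runReport <- function(pipeline, outDir, nullFeatures = 10000, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ranked <- pipeline$ranked
  utils::write.table(
    ranked[, c("feature_id", "folded_auc", "C1f", "C2f", "opm",
               "potentially_predictive")],
    file.path(outDir, "ranked_features.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  utils::write.csv(pipeline$screening$by_class,
                   file.path(outDir, "screening_by_class.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$screening$by_threshold,
                   file.path(outDir, "screening_by_threshold.csv"),
                   row.names = FALSE)
  lab <- SummarizedExperiment::colData(pipeline$matrix)$label
  null <- significanceNull(nullFeatures, lab, seed = seed)
  realOpm <- ranked$opm
  breaks <- seq(0, 1, by = 0.05)
  hReal <- graphics::hist(realOpm, breaks = breaks, plot = FALSE)
  utils::write.csv(
    data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1L],
               real_count = hReal$counts, null_count = null$histogram$count),
    file.path(outDir, "opm_histogram.csv"), row.names = FALSE)
  invisible(outDir)
}
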