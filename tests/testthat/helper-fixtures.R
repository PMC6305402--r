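# Shared fixtures: all built in code at test time.

# a random slide with <= nmax objects on a 1 mm square tissue, optionally a
# rectangular tumor annotation covering the lower-left quadrant
randomSlide <- function(seed, nmax = 200L, tumor = TRUE, edge = 1000) {
  set.seed(seed)
  n <- sample.int(nmax, 1L)
  marker <- sample(c("Ki67", "CD4", "CD8"), n, replace = TRUE)
  prolif <- ifelse(marker == "Ki67", TRUE, stats::runif(n) < 0.5)
  makeSlide(
    data.frame(x = stats::runif(n, 0, edge), y = stats::runif(n, 0, edge),
               marker = marker, proliferating = prolif),
    tissue = rectRing(0, 0, edge, edge),
    tumor = if (tumor) rectRing(0, 0, edge / 2, edge / 2) else NULL,
    slideId = paste0("rand", seed))
}

# a tiny deterministic slide with known counts per compartment
tinySlide <- function() {
  makeSlide(
    data.frame(
      x = c(100, 200, 300, 700, 800, 900, 250, 750),
      y = c(100, 200, 300, 700, 800, 900, 250, 750),
      marker = c("Ki67", "CD8", "CD4", "Ki67", "CD8", "CD4", "CD8", "CD8"),
      proliferating = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)),
    tissue = rectRing(0, 0, 1000, 1000),
    tumor = rectRing(0, 0, 500, 500),
    slideId = "tiny")
}

# small catalog configuration for fast end-to-end tests
smallConfig <- function(...) {
  rp <- defaultRatioPairs()[1:12, ]
  catalogConfig(ratioPairs = rp, nDistanceCombos = 12,
                thresholds = c(15, 50), ...)
}
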