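test_that("a 1 mm square tissue tiles exactly into 16 tiles of 250 um", {
  s <- tinySlide()
  g <- buildGrid(s, 250)
  t <- gridTiles(g)
  expect_equal(nrow(t), 16L)
  expect_true(all(abs(t$overlap - 250^2) < 1e-6))
  expect_equal(nrow(gridTiles(buildGrid(s, 500))), 4L)
  expect_equal(nrow(gridTiles(buildGrid(s, 1000))), 1L)
})

test_that("tiles with small tissue overlap are filtered at the 10% rule", {
  # tissue 1050 um wide: the last 250 um column has 50/250 = 20% overlap,
  # with a 1020 um width it would be 8% and must be dropped
  s20 <- makeSlide(data.frame(x = 10, y = 10, marker = "Ki67",
                              proliferating = TRUE),
                   tissue = rectRing(0, 0, 1050, 1000))
  expect_equal(nrow(gridTiles(buildGrid(s20, 250))), 20L)
  s08 <- makeSlide(data.frame(x = 10, y = 10, marker = "Ki67",
                              proliferating = TRUE),
                   tissue = rectRing(0, 0, 1020, 1000))
  expect_equal(nrow(gridTiles(buildGrid(s08, 250))), 16L)
  # the threshold is configurable
  expect_equal(nrow(gridTiles(buildGrid(s08, 250, overlapMin = 0.05))), 20L)
})

test_that("tumor scope keeps only tiles entirely inside the tumor", {
  s <- tinySlide()  # tumor = lower-left 500 x 500 quadrant
  gt <- buildGrid(s, 250, scope = "tumor_only")
  t <- gridTiles(gt)
  expect_equal(nrow(t), 4L)
  expect_true(all(t$xmax <= 500 & t$ymax <= 500))
  # tumor-scope tiles are a subset of the entire-scope tiles
  ge <- gridTiles(buildGrid(s, 250))
  expect_true(all(paste(t$xmin, t$ymin) %in% paste(ge$xmin, ge$ymin)))
  # no tumor: empty grid
  s2 <- generateVerificationSlide("A", seed = 1, nKi67 = 20, nCD8 = 5)
  expect_equal(nrow(gridTiles(buildGrid(s2, 250, scope = "tumor_only"))), 0L)
  # grid determinism
  expect_identical(gridTiles(buildGrid(s, 250)), gridTiles(buildGrid(s, 250)))
})

test_that("per-tile counts partition the slide-wide count on exact tilings", {
  for (seed in 30:33) {
    s <- randomSlide(seed, tumor = FALSE)  # tissue exactly tiled by 250 um
    g <- buildGrid(s, 250)
    base <- list(class = "count", num = "Tcell_any")
    v <- perTileValues(s, base, g)
    expect_equal(sum(v), countObjects(s, "Tcell_any", "entire"))
  }
})

test_that("per-tile values preserve IEEE non-finite semantics", {
  # 2 tiles: left holds 1 Ki67 + 1 CD8, right holds 1 Ki67 only
  s <- makeSlide(
    data.frame(x = c(100, 120, 300), y = c(100, 120, 100),
               marker = c("Ki67", "CD8", "Ki67"),
               proliferating = TRUE),
    tissue = rectRing(0, 0, 500, 250))
  g <- buildGrid(s, 250)
  ratio <- list(class = "ratio", num = "Ki67", den = "CD8_any")
  v <- perTileValues(s, ratio, g)
  expect_equal(v[1L], 1)
  expect_identical(v[2L], Inf)             # 1 / 0
  zz <- list(class = "ratio", num = "CD4_any", den = "CD4_any")
  v2 <- perTileValues(s, zz, g)
  expect_true(all(is.nan(v2)))             # 0 / 0
  # values match from-scratch recomputation
  cfg <- smallConfig()
  base <- icFeatures:::baseCatalog(cfg)
  for (i in c(1L, 5L, nrow(base))) {
    expect_equal(perTileValues(s, base[i, ], g),
                 oraclePerTile(s, base[i, ], g))
  }
})

test_that("dispersion measures reproduce hand-computed values", {
  expect_equal(hetCOV(c(1, 3)), sqrt(2) / 2)        # sample sd over mean
  expect_equal(hetCOV(rep(4, 5)), 0)
  expect_true(is.na(hetCOV(c(NaN, Inf))))           # nothing finite left
  expect_true(is.na(hetCOV(c(5))))                  # < 2 finite values
  expect_true(is.na(hetCOV(c(-1, 1))))              # zero mean
  expect_equal(hetQCD(1:5), 1 / 3)                  # (4 - 2) / (4 + 2)
  expect_equal(hetQCD(rep(7, 4)), 0)
  expect_true(is.na(hetQCD(c(0, 0, 0))))
  expect_equal(hetRP(1:100, 97), 97.03 / 50.5)      # linear interpolation
  expect_equal(hetRP(rep(3, 9), 5), 1)
  expect_true(is.na(hetRP(c(0, 0, 1), 90)))         # zero median
  # non-finite values are filtered before the statistics
  expect_equal(hetQCD(c(1:5, Inf, NaN)), 1 / 3)
})

test_that("COV and QCD are scale invariant; relative percentiles straddle 1", {
  for (seed in 40:44) {
    set.seed(seed)
    v <- rexp(20) + 0.1
    for (c in c(0.5, 3, 1000)) {
      expect_equal(hetCOV(c * v), hetCOV(v), tolerance = 1e-12)
      expect_equal(hetQCD(c * v), hetQCD(v), tolerance = 1e-12)
    }
    expect_lte(hetRP(v, 3), 1)
    expect_lte(hetRP(v, 3), hetRP(v, 10))
    expect_gte(hetRP(v, 97), 1)
    expect_gte(hetRP(v, 97), hetRP(v, 90))
  }
})

test_that("heterogeneity engine matches direct measure computation", {
  cfg <- smallConfig()
  hetCat <- heterogeneityCatalog(cfg)
  for (seed in 45:46) {
    s <- randomSlide(seed)
    got <- computeHeterogeneityFeatures(s, cfg, hetCat)
    # spot-check a deterministic sample of specs against the oracle
    set.seed(99)
    for (i in sample.int(nrow(hetCat), 40L)) {
      row <- hetCat[i, ]
      g <- buildGrid(s, row$edge, row$scope, cfg$overlapMin)
      want <- if (nrow(gridTiles(g)) == 0L) NA_real_
      else oracleMeasure(oraclePerTile(s, row, g), row$measure)
      expect_equal(got$value[i], want, tolerance = 1e-12,
                   label = row$feature_id)
    }
    expect_identical(is.na(got$value), got$reason != "none")
  }
})

test_that("uniform slides have near-equal tile densities, hotspots raise COV", {
  # paired comparison: same seed, one slide with a hotspot
  plain <- generateGenericSlide(tissueEdge = 1000, seed = 5,
                                intensities = list(CD8_prolif = 400))
  hot <- generateGenericSlide(tissueEdge = 1000, seed = 5,
                              intensities = list(CD8_prolif = 400),
                              hotspots = list(list(x = 375, y = 375,
                                                   radius = 120,
                                                   multiplier = 10)))
  g <- buildGrid(plain, 250)
  base <- list(class = "density", num = "CD8_prolif")
  covPlain <- hetCOV(perTileValues(plain, base, g))
  covHot <- hetCOV(perTileValues(hot, base, buildGrid(hot, 250)))
  expect_gt(covHot, covPlain)
})
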