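test_that("counts, densities and ratios follow their defining arithmetic", {
  s <- tinySlide()
  # tiny slide: tumor quadrant holds Ki67, CD8p, CD4n, CD8p; rest non-tumor
  expect_equal(countObjects(s, "Ki67", "entire"), 2L)
  expect_equal(countObjects(s, "CD8_prolif", "tumor"), 2L)
  expect_equal(countObjects(s, "CD8_any", "entire"), 4L)
  expect_equal(objectDensity(s, "Ki67", "entire"), 2)        # 2 per mm^2
  expect_equal(objectDensity(s, "CD8_prolif", "tumor"), 8)   # 2 / 0.25
  # fraction: subset over superset lies in [0, 1]
  expect_equal(countRatio(s, "CD8_prolif", "CD8_any"), 0.5)
  expect_equal(countRatio(s, "CD8_any", "CD8_any"), 1)
  expect_true(is.na(countRatio(s, "Ki67", "CD4_prolif", "tumor")))  # 0 denom
  # density x area = count exactly
  for (rg in c("entire", "tumor", "non_tumor"))
    expect_identical(objectDensity(s, "Tcell_any", rg) * regionAreas(s)[[rg]],
                     as.numeric(countObjects(s, "Tcell_any", rg)))
})

test_that("nearest-neighbour distances are exact and self-excluding", {
  s <- makeSlide(
    data.frame(x = c(0, 3, 100), y = c(0, 4, 100),
               marker = c("Ki67", "CD8", "CD8"),
               proliferating = TRUE),
    tissue = rectRing(0, 0, 1000, 1000))
  d <- nnDistance(s, "CD8_prolif")
  expect_equal(d[1L], 5)                         # 3-4-5 triangle
  expect_equal(d[2L], sqrt(97^2 + 96^2))         # self excluded
  expect_equal(nnDistance(s, "CD4_any"), rep(Inf, 3))  # empty set
  # empty reference set: LE counts 0, GT counts all
  expect_equal(countWithCriterion(s, "Ki67",
                                  distanceCriterion("CD4_any", "LE", 50)), 0L)
  expect_equal(countWithCriterion(s, "Ki67",
                                  distanceCriterion("CD4_any", "GT", 50)), 1L)
})

test_that("fast NN path matches the O(n^2) oracle on random slides", {
  for (seed in 1:6) {
    s <- randomSlide(seed)
    o <- cellData(s)
    for (set in c("Ki67", "CD8_any", "Tcell_prolif")) {
      member <- setMembership(o, set)
      expect_equal(nnDistance(s, set), oracleNN(o, member),
                   tolerance = 1e-12)
    }
  }
})

test_that("criterion counts match exhaustive recomputation incl. AND/OR", {
  for (seed in 7:12) {
    s <- randomSlide(seed)
    o <- cellData(s)
    for (comb in c("OR", "AND")) for (dir in c("LE", "GT")) {
      crit <- distanceCriterion("CD4_any+CD8_any", dir, 30, comb)
      refs <- lapply(c("CD4_any", "CD8_any"),
                     function(x) setMembership(o, x))
      want <- sum(setMembership(o, "Ki67") &
                    o$compartment == "tumor" &
                    oracleCriterion(o, refs, comb, dir, 30))
      expect_identical(countWithCriterion(s, "Ki67", crit, "tumor"),
                       as.integer(want))
    }
  }
})

test_that("criterion identities hold on random slides", {
  for (seed in 13:18) {
    s <- randomSlide(seed)
    n <- countObjects(s, "Tcell_any", "entire")
    # complement: #(<= theta) + #(> theta) = unrestricted count
    for (theta in c(15, 35, 100)) {
      le <- countWithCriterion(s, "Tcell_any",
                               distanceCriterion("Ki67", "LE", theta))
      gt <- countWithCriterion(s, "Tcell_any",
                               distanceCriterion("Ki67", "GT", theta))
      expect_identical(le + gt, n)
    }
    # multi-set complement: OR(<=) complements AND(>)
    or_le <- countWithCriterion(s, "Ki67",
      distanceCriterion("CD4_any+CD8_any", "LE", 30, "OR"))
    and_gt <- countWithCriterion(s, "Ki67",
      distanceCriterion("CD4_any+CD8_any", "GT", 30, "AND"))
    expect_identical(or_le + and_gt, countObjects(s, "Ki67", "entire"))
    # monotone in theta; OR dominates AND for <=
    les <- vapply(c(15, 20, 35, 50, 100), function(t)
      countWithCriterion(s, "Ki67", distanceCriterion("CD8_any", "LE", t)),
      0L)
    expect_true(all(diff(les) >= 0L))
    gts <- vapply(c(15, 20, 35, 50, 100), function(t)
      countWithCriterion(s, "Ki67", distanceCriterion("CD8_any", "GT", t)),
      0L)
    expect_true(all(diff(gts) <= 0L))
    or2 <- countWithCriterion(s, "Ki67",
      distanceCriterion("CD4_any+CD8_any", "LE", 30, "OR"))
    and2 <- countWithCriterion(s, "Ki67",
      distanceCriterion("CD4_any+CD8_any", "LE", 30, "AND"))
    expect_gte(or2, and2)
    # |M| = 1: OR and AND coincide
    expect_identical(
      countWithCriterion(s, "CD8_any", distanceCriterion("Ki67", "LE", 25, "OR")),
      countWithCriterion(s, "CD8_any", distanceCriterion("Ki67", "LE", 25, "AND")))
  }
})

test_that("theta beyond the slide diagonal reduces LE counts to plain counts", {
  s <- randomSlide(19)
  crit <- distanceCriterion("Ki67", "LE", 5000)
  # every object with a nonempty reference set qualifies
  expect_identical(countWithCriterion(s, "CD8_any", crit),
                   countObjects(s, "CD8_any"))
})

test_that("distance ratios follow the shared-criterion contract", {
  s <- randomSlide(20)
  crit <- distanceCriterion("Ki67", "LE", 35)
  # numerator set = denominator set with criterion on both: 1 when count > 0
  v <- distanceRatio(s, "CD8_any", "CD8_any", crit, denCriterion = TRUE)
  nWith <- countWithCriterion(s, "CD8_any", crit)
  if (nWith > 0) expect_equal(v, 1) else expect_true(is.na(v))
  # fraction form is bounded by 1
  f <- distanceRatio(s, "CD8_any", "CD8_any", crit)
  expect_true(is.na(f) || (f >= 0 && f <= 1))
})

test_that("whole-catalog evaluation agrees with per-spec recomputation", {
  cfg <- smallConfig()
  cat <- featureCatalog(cfg)
  for (seed in 21:24) {
    s <- randomSlide(seed, tumor = seed %% 2L == 0L)
    got <- computeGlobalFeatures(s, cfg, cat)
    want <- vapply(seq_len(nrow(cat)), function(i)
      oracleGlobalValue(s, cat[i, ]), 0)
    expect_equal(got$value, want, tolerance = 1e-12)
    # unavailability is explicit and consistent
    expect_identical(is.na(got$value), got$reason != "none")
  }
})

test_that("tumor-less slides report tumor features as region_missing", {
  s <- generateVerificationSlide("A", seed = 3, nKi67 = 30, nCD8 = 5)
  got <- computeGlobalFeatures(s, smallConfig())
  cat <- featureCatalog(smallConfig())
  expect_true(all(got$reason[cat$region == "tumor"] == "region_missing"))
  expect_true(all(is.na(got$value[cat$region == "tumor"])))
  # recomputation is idempotent
  expect_identical(got, computeGlobalFeatures(s, smallConfig()))
})
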