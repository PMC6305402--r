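test_that("folded AUC handles separation, identity and the folding rule", {
  expect_equal(foldedAUC(1:5, 6:10), 1)       # perfect separation, folded
  expect_equal(foldedAUC(6:10, 1:5), 1)
  expect_equal(foldedAUC(c(1, 2, 3), c(1, 2, 3)), 0.5)  # identical multisets
  # raw AUC 0.3 folds to 0.7: 3 of 10 comparisons won by class 1
  v1 <- c(1, 2); v2 <- c(1.5, 1.6, 1.7, 2.5, 2.6)
  r <- rank(c(v1, v2))
  raw <- (sum(r[1:2]) - 3) / 10
  expect_equal(foldedAUC(v1, v2), max(raw, 1 - raw))
  expect_equal(foldedAUC(v1, v2), 0.7)
  # unavailable values are dropped; empty class is unrankable
  expect_equal(foldedAUC(c(NA, 1, 2), c(3, 4, NA)), 1)
  expect_true(is.na(foldedAUC(c(NA, NA), 1:3)))
})

test_that("folded AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    v1 <- rnorm(13, mean = runif(1, -1, 1))
    v2 <- rnorm(21)
    ref <- suppressMessages(pROC::auc(
      pROC::roc(c(rep(0, 13), rep(1, 21)), c(v1, v2), quiet = TRUE)))
    expect_equal(foldedAUC(v1, v2), max(as.numeric(ref), 1 - as.numeric(ref)),
                 tolerance = 1e-12)
  }
  # ties counted one half: 1 win + 4 ties of 9 pairs -> AUC 3/9, folded 2/3
  expect_equal(foldedAUC(c(1, 1, 2), c(1, 2, 2)), 2 / 3)
  expect_equal(foldedAUC(c(1, 2), c(1, 2)), 0.5)
})

test_that("OPM follows its defining arithmetic", {
  expect_equal(opm(0.5, 19, 53), 0)
  expect_equal(opm(0.5, 19, 53, 3, 7), 0)
  expect_equal(opm(1.0, 10, 10), 1)
  expect_equal(opm(1.0, 10, 10, 5, 5), 0.25)
  expect_equal(opm(0.75, 20, 40, 10, 30), 2 * 0.25 * 0.5 * 0.75)
  expect_equal(opm(NA, 10, 10), 0)           # unrankable
  expect_error(opm(0.8, 0, 10), "class")
  # monotone in folded AUC and in each availability fraction
  expect_lt(opm(0.8, 10, 10, 5, 10), opm(0.9, 10, 10, 5, 10))
  expect_lt(opm(0.8, 10, 10, 5, 10), opm(0.8, 10, 10, 6, 10))
})

test_that("ranking is invariant to monotone transforms and label swaps", {
  set.seed(21)
  res <- lapply(1:12, function(i) {
    v <- c(rnorm(6, 2), rnorm(6))
    data.frame(feature_id = c("a", "b", "c"),
               value = c(v[i %% 6 + 1], exp(v[i %% 6 + 1]), rnorm(1)),
               reason = "none")
  })
  names(res) <- sprintf("s%02d", 1:12)
  labels <- data.frame(slide_id = names(res),
                       label = rep(c("MSI", "MSS"), each = 6))
  se <- buildFeatureMatrix(res, labels)
  ranked <- rankFeatures(se)
  # feature b is exp(feature a): identical folded AUC and OPM
  expect_equal(ranked$opm[ranked$feature_id == "a"],
               ranked$opm[ranked$feature_id == "b"])
  # swapping class labels changes nothing
  labels2 <- labels
  labels2$label <- rep(c("MSS", "MSI"), each = 6)
  ranked2 <- rankFeatures(buildFeatureMatrix(res, labels2))
  expect_equal(ranked$opm, ranked2$opm)
  expect_equal(ranked$folded_auc, ranked2$folded_auc)
  # descending OPM with deterministic tie-break
  expect_true(all(diff(ranked$opm) <= 0))
})

test_that("constant features rank at the bottom with OPM 0", {
  res <- lapply(1:8, function(i)
    data.frame(feature_id = c("const", "informative"),
               value = c(5, as.numeric(i <= 4)), reason = "none"))
  names(res) <- sprintf("s%d", 1:8)
  labels <- data.frame(slide_id = names(res),
                       label = rep(c("A", "B"), each = 4))
  ranked <- rankFeatures(buildFeatureMatrix(res, labels))
  expect_equal(ranked$feature_id, c("informative", "const"))
  expect_equal(ranked$opm, c(1, 0))
})

test_that("availability scales OPM through the feature matrix", {
  # feature perfectly separating but available on half of each class
  res <- lapply(1:8, function(i)
    data.frame(feature_id = "f",
               value = if (i %% 2 == 0) NA_real_ else as.numeric(i <= 4),
               reason = if (i %% 2 == 0) "region_missing" else "none"))
  names(res) <- sprintf("s%d", 1:8)
  labels <- data.frame(slide_id = names(res),
                       label = rep(c("A", "B"), each = 4))
  ranked <- rankFeatures(buildFeatureMatrix(res, labels))
  expect_equal(ranked$C1f, 2L)
  expect_equal(ranked$C2f, 2L)
  expect_equal(ranked$opm, 1 * 0.5 * 0.5)
})

test_that("null OPM distribution is calibrated and reproducible", {
  labels <- rep(c("MSI", "MSS"), c(19, 53))
  null1 <- significanceNull(2000, labels, seed = 101, thresholds = c(0.4, 0.6))
  null2 <- significanceNull(2000, labels, seed = 101, thresholds = c(0.4, 0.6))
  expect_identical(null1$opm, null2$opm)       # seeded reproducibility
  null3 <- significanceNull(2000, labels, seed = 102)
  expect_false(identical(null1$opm, null3$opm))
  # same distributional shape across seeds
  expect_equal(mean(null1$opm), mean(null3$opm), tolerance = 0.15)
  # exceedances are monotone in the threshold
  expect_gte(null1$exceedance[["0.4"]], null1$exceedance[["0.6"]])
  expect_error(significanceNull(10, rep("A", 5)), "two classes")
})

test_that("uniform null features rarely reach the screening threshold", {
  # empirical P(OPM >= 0.6) < 1e-3 for the 19/53 class split
  labels <- rep(c("MSI", "MSS"), c(19, 53))
  total <- 0L
  for (seed in 201:205)
    total <- total + significanceNull(20000, labels,
                                      seed = seed)$exceedance[["0.6"]]
  expect_lt(total / 1e5, 1e-3)
})
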