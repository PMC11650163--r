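test_that("an effectively infinite penalty yields an empty, flagged selection", {
  cohort <- simulateCohort(smallConfig(seed = 1))
  tr <- trainingMatrix(cohort)
  expect_warning(
    sel <- selectFeatures(tr$x, tr$condition, tr$subject,
                          lambdaGrid = 1e6, seed = 1),
    "empty")
  expect_true(sel@empty)
  expect_length(regionIds(sel), 0L)
})

test_that("the largest grid penalty keeps no more features than the smallest", {
  cohort <- simulateCohort(smallConfig(seed = 4))
  tr <- trainingMatrix(cohort)
  grid <- exp(seq(log(0.5), log(1e-3), length.out = 10))
  sizes <- vapply(c(grid[1], grid[10]), function(lam)
    length(regionIds(suppressWarnings(
      selectFeatures(tr$x, tr$condition, tr$subject, lambdaGrid = lam)))),
    numeric(1))
  expect_lte(sizes[1], sizes[2])
})

test_that("high-SNR selection recovers mostly true discriminative regions", {
  cfg <- smallConfig(seed = 6, deltaReward = 1.5, deltaPunishment = 1.5,
                     noiseSd = 0.5)
  cohort <- simulateCohort(cfg)
  tr <- trainingMatrix(cohort)
  sel <- selectFeatures(tr$x, tr$condition, tr$subject, seed = 6)
  truth <- with(groundTruth(cohort), c(rewardRegions, punishmentRegions))
  expect_gt(length(regionIds(sel)), 0L)
  expect_gt(mean(regionIds(sel) %in% truth), 0.5)
  # signs follow the generative contrast direction
  signs <- selectionSigns(sel)
  trueRew <- intersect(names(signs), groundTruth(cohort)$rewardRegions)
  truePun <- intersect(names(signs), groundTruth(cohort)$punishmentRegions)
  expect_true(all(signs[trueRew] == 1L))
  expect_true(all(signs[truePun] == -1L))
})

test_that("selection is untouched by non-training rows (no leakage)", {
  cohort <- simulateCohort(smallConfig(seed = 8))
  h1 <- trainClassifier(cohort, seed = 2)
  ft <- featureTable(cohort)
  ph <- phenotypes(cohort)
  outside <- !ft$subject_id %in% ph$subject_id[ph$group == "TD_train"]
  ft[outside, -(1:2)] <- ft[sample(which(outside)), -(1:2)] * 3 + 1
  h2 <- trainClassifier(rewardCohort(ft, ph), seed = 2)
  expect_identical(regionIds(h1@selection), regionIds(h2@selection))
  expect_identical(weights(h1), weights(h2))
  expect_identical(intercept(h1), intercept(h2))
})

test_that("selection rejects bad inputs", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(selectFeatures(x, rep("reward", 10), rep(letters[1:5], 2)),
               "both conditions")
  expect_error(selectFeatures(x, rep(c("reward", "up"), 5),
                              rep(letters[1:5], 2)), "condition labels")
})
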