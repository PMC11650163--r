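test_that("two separable points recover the perpendicular bisector", {
  x <- rbind(c(2, 0), c(-2, 0))
  colnames(x) <- c("A", "B")
  h <- fitHyperplane(x, c("reward", "punishment"), C = 1e6)
  d <- signedDistance(h, x)
  expect_equal(unname(d), c(2, -2), tolerance = 1e-4)
  # boundary is x1 = 0: the second weight vanishes
  w <- weights(h) / rewardDFH:::l2norm(weights(h))
  expect_equal(unname(w), c(1, 0), tolerance = 1e-4)
  expect_equal(intercept(h) / rewardDFH:::l2norm(weights(h)), 0,
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(fitHyperplane(x, rep("reward", 4)), "both condition")
  x[1] <- Inf
  expect_error(fitHyperplane(x, rep(c("reward", "punishment"), 2)),
               "finite")
  expect_error(fitHyperplane(x, rep(c("reward", "punishment"), 2), C = -1))
})

test_that("duplicating every observation with C halved leaves the fit alone", {
  set.seed(10)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  x[1:15, 1] <- x[1:15, 1] + 2.5
  cond <- rep(c("reward", "punishment"), each = 15)
  h1 <- fitHyperplane(x, cond, C = 1)
  h2 <- fitHyperplane(rbind(x, x), c(cond, cond), C = 0.5)
  expect_equal(weights(h2), weights(h1), tolerance = 1e-6)
  expect_equal(intercept(h2), intercept(h1), tolerance = 1e-6)
})

test_that("orientation invariant: reward side is positive after every fit", {
  for (s in 1:5) {
    cohort <- simulateCohort(smallConfig(seed = s))
    h <- trainClassifier(cohort, seed = s)
    tr <- trainingMatrix(cohort)
    d <- signedDistance(h, tr$x[, regionIds(h), drop = FALSE])
    expect_gt(mean(d[tr$condition == "reward"]), 0)
  }
})

test_that("confusion counts map to the definitional metrics", {
  cv <- cvResult(c(TP = 9L, FN = 1L, TN = 8L, FP = 2L))
  expect_equal(cv@sensitivity, 0.90)
  expect_equal(cv@specificity, 0.80)
  expect_equal(cv@accuracy, 0.85)
})

test_that("grouped CV is accurate on near-separable data and invariant to row order", {
  cfg <- smallConfig(seed = 12, deltaReward = 1.5, deltaPunishment = 1.5,
                     noiseSd = 0.5)
  cohort <- simulateCohort(cfg)
  cv1 <- groupedCvEvaluate(cohort, k = 5, seed = 3)
  expect_gte(cv1@accuracy, 0.9)
  # shuffle the subject blocks in the feature table and re-evaluate
  ft <- featureTable(cohort)
  perm <- withr::with_seed(99, sample(unique(ft$subject_id)))
  ft2 <- do.call(rbind, lapply(perm, function(s) ft[ft$subject_id == s, ]))
  cv2 <- groupedCvEvaluate(rewardCohort(ft2, phenotypes(cohort)),
                           k = 5, seed = 3)
  expect_identical(cv1@confusion, cv2@confusion)
  # every subject's two observations share a fold, folds partition subjects
  expect_setequal(unlist(cv1@foldSubjects),
                  phenotypes(cohort)$subject_id[
                    phenotypes(cohort)$group == "TD_train"])
  expect_false(anyDuplicated(unlist(cv1@foldSubjects)) > 0)
})

test_that("rescaling the hyperplane changes no decision or distance", {
  cohort <- simulateCohort(smallConfig(seed = 2))
  h <- trainClassifier(cohort, seed = 2)
  scaled <- methods::new("Hyperplane", weights = 3.7 * h@weights,
    intercept = 3.7 * h@intercept, regionIds = h@regionIds,
    standardizer = h@standardizer, selection = h@selection,
    orientation = "reward_positive", cost = h@cost)
  expect_equal(signedDistance(scaled, cohort), signedDistance(h, cohort),
               tolerance = 1e-12)
})
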