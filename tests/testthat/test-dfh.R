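mkPlane <- function(w, b) {
  methods::new("Hyperplane", weights = setNames(w, paste0("R", seq_along(w))),
               intercept = b, regionIds = paste0("R", seq_along(w)),
               standardizer = NULL, selection = NULL,
               orientation = "reward_positive", cost = 1)
}

test_that("signed distance follows the plane geometry", {
  # on-plane point
  h <- mkPlane(c(1, 2), -5)
  expect_equal(signedDistance(h, c(1, 2)), 0)
  # x parallel to w: |w.x| / ||w|| = 25 / 5
  expect_equal(signedDistance(mkPlane(c(3, 4), 0), c(3, 4)), 5)
  # generic point, geometric value
  expect_equal(signedDistance(mkPlane(c(1, 1), -1), c(2, 0)),
               0.70711, tolerance = 1e-5)
  expect_error(signedDistance(h, c(1, 2, 3)), "dimension")
  expect_error(signedDistance(h, c(NA, 1)), "finite")
})

test_that("norm reference has the hand-computed moments", {
  ref <- buildNormReference(c(1, 2, 3))
  expect_equal(ref@mu, 2)
  expect_equal(ref@sigma, 1)   # ddof = 1
  expect_equal(ref@n, 3L)
  expect_error(buildNormReference(rep(4, 5)), "degenerate")
  expect_error(buildNormReference(1), ">= 2")
})

test_that("self-norming the training distances gives mean 0, s.d. 1", {
  set.seed(21)
  d <- rnorm(65, 1.4, 0.8)
  z <- normDistance(buildNormReference(d), d)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
})

test_that("category boundaries assign ties to the inner bin", {
  expect_equal(as.character(categorizeZ(0)), "normative")
  expect_equal(as.character(categorizeZ(-2.5)), "below_minus2")
  expect_equal(as.character(categorizeZ(1.0)), "normative")
  expect_equal(as.character(categorizeZ(-1.0)), "normative")
  expect_equal(as.character(categorizeZ(2.0)), "plus1_to_plus2")
  expect_equal(as.character(categorizeZ(-2.0)), "minus2_to_minus1")
  expect_error(categorizeZ(NaN), "finite")
})

test_that("the five categories partition the reals", {
  set.seed(33)
  z <- c(rnorm(2000, 0, 3), runif(2000, -10, 10),
         as.vector(outer(c(-2, -1, 1, 2), c(-1e-9, 0, 1e-9), "+")))
  cats <- categorizeZ(z)
  expect_false(anyNA(cats))
  expect_equal(nlevels(cats), 5L)
  # bin edges are honored exactly
  expect_true(all(cats[z > 2] == "above_plus2"))
  expect_true(all(cats[z < -2] == "below_minus2"))
  expect_true(all(cats[z >= -1 & z <= 1] == "normative"))
})

test_that("clinical mean normed reward z falls as attenuation deepens", {
  meanZ <- sapply(1:3, function(s) {
    vapply(c(1.0, 0.7, 0.4), function(lam) {
      cfg <- smallConfig(seed = s,
        attenuation = c(CD = lam, ADHD = lam, MDD = lam, GAD = lam))
      cohort <- simulateCohort(cfg)
      h <- trainClassifier(cohort, seed = s)
      dfh <- scoreCohort(cohort, h)
      mean(dfh$z[dfh$group == "clinical" & dfh$condition == "reward"])
    }, numeric(1))
  })
  avg <- rowMeans(meanZ)
  expect_true(all(diff(avg) < 0))        # deeper attenuation, lower z
  expect_lt(avg[3], avg[1] - 0.5)        # lambda 0.4 is clearly deficient
})

test_that("scoring records are complete and consistent", {
  cohort <- simulateCohort(smallConfig(seed = 14))
  h <- trainClassifier(cohort, seed = 14)
  dfh <- scoreCohort(cohort, h)
  ref <- attr(dfh, "reference")
  expect_equal(nrow(dfh), 2 * length(subjectIds(cohort)))
  isRew <- dfh$condition == "reward"
  expect_equal(dfh$z[isRew], (dfh$d[isRew] - ref@mu) / ref@sigma)
  expect_true(all(is.na(dfh$z[!isRew])))
  expect_true(all(is.na(dfh$category[!isRew])))
  expect_equal(dfh$d_pun[!isRew], -dfh$d[!isRew])
  # training reward rows self-norm to mean 0 sd 1
  trainZ <- dfh$z[isRew & dfh$group == "TD_train"]
  expect_lt(abs(mean(trainZ)), 1e-10)
  expect_lt(abs(sd(trainZ) - 1), 1e-10)
})
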