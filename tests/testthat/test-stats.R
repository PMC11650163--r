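test_that("category tables bin groups directly", {
  dfh <- dfhRecords(c("t1", "t2", "t3", "c1", "c2"),
                    z = c(0, 0, 0, -3, -3))
  ph <- data.frame(subject_id = c("t1", "t2", "t3", "c1", "c2"),
                   group = factor(c(rep("TD_test", 3), rep("clinical", 2)),
                                  levels = c("TD_train", "TD_test",
                                             "clinical")))
  tab <- categoryTable(dfh, ph, c("TD_test", "clinical"))
  expect_equal(unname(tab["TD_test", ]), c(0L, 0L, 3L, 0L, 0L))
  expect_equal(unname(tab["clinical", ]), c(2L, 0L, 0L, 0L, 0L))
  expect_error(categoryTable(dfh, ph, c("TD_test", "OCD")),
               "unknown group")
})

test_that("diagnosis groups count comorbid subjects in each comparison", {
  ph <- data.frame(
    subject_id = c("t1", "c1", "c2"),
    group = factor(c("TD_test", "clinical", "clinical"),
                   levels = c("TD_train", "TD_test", "clinical")),
    CD = c(FALSE, TRUE, TRUE), ADHD = c(FALSE, TRUE, FALSE),
    MDD = FALSE, GAD = FALSE)
  dfh <- dfhRecords(c("t1", "c1", "c2"), z = c(0, -3, -1.5))
  tabCD <- categoryTable(dfh, ph, c("TD_test", "CD"))
  tabADHD <- categoryTable(dfh, ph, c("TD_test", "ADHD"))
  expect_equal(sum(tabCD["CD", ]), 2L)     # both CD subjects
  expect_equal(sum(tabADHD["ADHD", ]), 1L) # the comorbid one again
})

test_that("bin collapsing keeps the scheme's columns and reports drops", {
  tab <- rbind(a = c(0L, 1L, 3L, 1L, 0L), b = c(2L, 3L, 5L, 0L, 0L))
  colnames(tab) <- levels(categorizeZ(0))
  expect_equal(unname(collapseBins(tab, "full5")), unname(tab),
               ignore_attr = TRUE)
  low <- collapseBins(tab, "low3")
  expect_equal(unname(low), rbind(c(3L, 1L, 0L), c(5L, 3L, 2L)),
               ignore_attr = TRUE)
  expect_equal(colnames(low),
               c("normative", "minus2_to_minus1", "below_minus2"))
  expect_equal(attr(low, "dropped"), 1L)
  expect_error(collapseBins(tab, "mid2"))
})

test_that("chi-square matches hand computations and handles degeneracy", {
  r1 <- chiSquareTest(rbind(c(10, 20), c(20, 10)))
  expect_equal(r1$statistic, 6.6667, tolerance = 1e-3)
  expect_equal(r1$df, 1L)
  # proportional rows are perfectly homogeneous
  r2 <- chiSquareTest(rbind(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$df, 2L)
  # invented 5x2 table against the direct-formula value
  r3 <- chiSquareTest(rbind(c(2, 5, 28, 3, 1), c(10, 25, 120, 25, 15)))
  expect_equal(r3$statistic, 2.506, tolerance = 0.01)
  expect_equal(r3$df, 4L)
  expect_equal(r3$n, 234)
  # zero-total column dropped with df adjustment
  tab <- rbind(c(5, 0, 7), c(3, 0, 9))
  expect_warning(r4 <- chiSquareTest(tab), "dropping")
  expect_equal(r4$df, 1L)
  # all-empty high bins: degenerate, NA statistic
  degen <- collapseBins(rbind(c(1L, 2L, 5L, 0L, 0L),
                              c(3L, 1L, 6L, 0L, 0L)), "high3")
  expect_warning(r5 <- chiSquareTest(degen), "degenerate|dropping")
  expect_true(is.na(r5$statistic))
})

test_that("chi-square equals the brute-force O/E formula on random tables", {
  bruteChi <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  set.seed(77)
  for (i in 1:50) {
    tab <- matrix(rpois(10, 8) + 1, 2, 5)
    expect_equal(chiSquareTest(tab)$statistic, bruteChi(tab),
                 tolerance = 1e-8)
  }
})

test_that("correlations reproduce the textbook toy values", {
  ph <- data.frame(subject_id = paste0("s", 1:4),
                   group = factor(rep("clinical", 4),
                                  levels = c("TD_train", "TD_test",
                                             "clinical")),
                   exact = c(2, 4, 6, 8) / 2, wiggly = c(1, 3, 2, 4))
  dfh <- dfhRecords(paste0("s", 1:4), z = c(1, 2, 3, 4))
  out <- correlateDFH(dfh, ph, variables = c("exact", "wiggly"))
  rew <- out[out$condition == "reward", ]
  expect_equal(rew$r[rew$variable == "exact"], 1.0)
  expect_equal(rew$r[rew$variable == "wiggly"], 0.8)
  expect_equal(rew$n, c(4L, 4L))
  # fewer than 3 complete pairs is reported as not computable
  ph$sparse <- c(5, NA, NA, NA)
  out2 <- correlateDFH(dfh, ph, variables = "sparse")
  expect_true(all(is.na(out2$r)))
})

test_that("symptom severity comparison is a Welch t test", {
  ids <- paste0("s", 1:6)
  dfh <- dfhRecords(ids, z = c(0, 0, 0, -2.5, -2.5, -2.5))
  ph <- data.frame(subject_id = ids,
                   group = factor(rep("clinical", 6),
                                  levels = c("TD_train", "TD_test",
                                             "clinical")),
                   scaleA = c(1, 2, 3, 4, 5, 6),
                   scaleB = c(1, 2, 3, 1, 2, 3))
  resA <- compareSymptomSeverity(dfh, ph, "scaleA")
  expect_equal(resA$t, -3.674, tolerance = 1e-3)
  expect_equal(resA$mean_typical, 2)
  expect_equal(resA$mean_deficient, 5)
  expect_equal(resA$n_typical, 3L)
  resB <- compareSymptomSeverity(dfh, ph, "scaleB")
  expect_equal(resB$t, 0)
  # the looser deficiency definition pulls in the -1..-2 band
  dfh2 <- dfhRecords(ids, z = c(0, 0, 0, -1.5, -2.5, -2.5))
  res2 <- compareSymptomSeverity(dfh2, ph, "scaleA",
                                 deficientDef = "below_minus1")
  expect_equal(res2$n_deficient, 3L)
  expect_error(compareSymptomSeverity(dfh, ph, "nope"), "unknown scale")
})

test_that("covariate adjustment behaves like OLS should", {
  set.seed(5)
  g <- factor(rep(c("typical", "deficient"), each = 20),
              levels = c("typical", "deficient"))
  age <- rnorm(40, 15, 2)
  # outcome exactly a covariate: group coefficient vanishes
  res <- covariateAdjustedComparison(age, g, data.frame(age = age))
  expect_lt(abs(res$adjusted$estimate), 1e-8)
  # covariates independent of group: adjusted tracks unadjusted
  diffs <- replicate(20, {
    y <- rnorm(40) + 2 * (g == "deficient")
    r <- covariateAdjustedComparison(y, g,
      data.frame(age = rnorm(40, 15, 2)))
    r$adjusted$estimate - r$unadjusted$estimate
  })
  expect_lt(abs(mean(diffs)), 0.1)
  # collinear covariates are flagged and the adjusted model skipped
  expect_warning(
    res3 <- covariateAdjustedComparison(rnorm(40), g,
      data.frame(a = age, b = 2 * age)),
    "collinear")
  expect_true(is.na(res3$adjusted$estimate))
})

test_that("induced age confounding shrinks the adjusted group effect", {
  cohort <- simulateCohort(smallConfig(seed = 19, nClinical = 60L,
                                       confoundAge = TRUE))
  h <- trainClassifier(cohort, seed = 19)
  dfh <- scoreCohort(cohort, h)
  ph <- phenotypes(cohort)
  testIds <- ph$subject_id[ph$group %in% c("TD_test", "clinical")]
  grp <- rewardDFH:::splitByDeficiency(dfh, testIds, "below_minus1")
  ids <- c(grp$typical, grp$deficient)
  gvec <- factor(rep(c("typical", "deficient"),
                     c(length(grp$typical), length(grp$deficient))),
                 levels = c("typical", "deficient"))
  idx <- match(ids, ph$subject_id)
  res <- covariateAdjustedComparison(ph$SDQ_CP[idx], gvec,
                                     ph[idx, "age", drop = FALSE])
  expect_lt(abs(res$adjusted$estimate), abs(res$unadjusted$estimate))
})
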