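test_that("default configuration produces the study-sized cohort", {
  cohort <- simulateCohort(simulationConfig(seed = 1))
  ft <- featureTable(cohort)
  expect_equal(nrow(ft), 2 * (65 + 39 + 195))
  expect_equal(ncol(ft) - 2L, 412L)
  ph <- phenotypes(cohort)
  expect_equal(as.vector(table(ph$group)), c(65L, 39L, 195L))
  # every subject has one row per condition
  expect_true(all(table(ft$subject_id, ft$condition) == 1L))
  # every clinical subject carries at least one diagnosis flag
  clin <- ph[ph$group == "clinical", c("CD", "ADHD", "MDD", "GAD")]
  expect_true(all(rowSums(clin) >= 1L))
  # the last 12 region labels are subcortical structures
  expect_equal(sum(grepl("^Parcel_", regionIds(cohort))), 400L)
})

test_that("identical seed gives a bit-identical cohort", {
  a <- simulateCohort(smallConfig(seed = 42))
  b <- simulateCohort(smallConfig(seed = 42))
  expect_identical(featureTable(a), featureTable(b))
  expect_identical(phenotypes(a), phenotypes(b))
  expect_identical(groundTruth(a), groundTruth(b))
  c <- simulateCohort(smallConfig(seed = 43))
  expect_false(identical(featureTable(a), featureTable(c)))
})

test_that("attenuation touches only the reward condition", {
  cfgDefault <- smallConfig(seed = 7)
  cfgNull <- smallConfig(seed = 7,
    attenuation = c(CD = 1, ADHD = 1, MDD = 1, GAD = 1))
  a <- simulateCohort(cfgDefault)
  b <- simulateCohort(cfgNull)
  ftA <- featureTable(a); ftB <- featureTable(b)
  pun <- ftA$condition == "punishment"
  # punishment rows are identical draw for draw across attenuation settings
  expect_identical(ftA[pun, ], ftB[pun, ])
  expect_false(identical(ftA[!pun, ], ftB[!pun, ]))
})

test_that("mean reward signal on reward regions decreases with 1 - lambda", {
  means <- vapply(c(1.0, 0.7, 0.4), function(lam) {
    cfg <- smallConfig(seed = 11, nClinical = 400L,
      attenuation = c(CD = lam, ADHD = lam, MDD = lam, GAD = lam))
    cohort <- simulateCohort(cfg)
    ft <- featureTable(cohort)
    ph <- phenotypes(cohort)
    clin <- ph$subject_id[ph$group == "clinical"]
    rew <- ft$condition == "reward" & ft$subject_id %in% clin
    mean(as.matrix(ft[rew, groundTruth(cohort)$rewardRegions]))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("lambda = 1 with zero symptom coupling removes all group signal", {
  beta0 <- stats::setNames(rep(0, 15), rewardDFH:::scaleNames())
  pvals <- vapply(1:100, function(s) {
    cfg <- smallConfig(seed = s, nRegions = 34L, rewardRegions = 1:8,
      punishmentRegions = 9:14,
      attenuation = c(CD = 1, ADHD = 1, MDD = 1, GAD = 1),
      symptomBeta = beta0)
    cohort <- simulateCohort(cfg)
    ft <- featureTable(cohort)
    ph <- phenotypes(cohort)
    rewRegions <- groundTruth(cohort)$rewardRegions
    contrast <- vapply(split(seq_len(nrow(ft)), ft$subject_id),
      function(i) {
        rows <- ft[i, ]
        mean(as.numeric(rows[rows$condition == "reward", rewRegions])) -
          mean(as.numeric(rows[rows$condition == "punishment", rewRegions]))
      }, numeric(1))
    grp <- ph$group[match(names(contrast), ph$subject_id)]
    stats::t.test(contrast[grp == "clinical"],
                  contrast[grp != "clinical"])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.95)
})

test_that("symptom scores are exactly affine in (1 - gain) without noise", {
  zeroSd <- stats::setNames(rep(0, 15), rewardDFH:::scaleNames())
  cohort <- simulateCohort(smallConfig(seed = 3, symptomNoiseSd = zeroSd))
  ph <- phenotypes(cohort)
  g <- groundTruth(cohort)$g[ph$subject_id]
  defs <- rewardDFH:::scaleDefinitions()
  for (sc in c("SDQ_CP", "CDI", "Conners_ADHD")) {
    expected <- defs[sc, "intercept"] + defs[sc, "beta"] * (1 - g)
    expect_equal(unname(ph[[sc]]), unname(expected), tolerance = 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(smallConfig(rewardRegions = 1:8, punishmentRegions = 8:12),
               "disjoint")
  expect_error(smallConfig(
    attenuation = c(CD = 1.2, ADHD = 1, MDD = 1, GAD = 1)), "0, 1")
  expect_error(smallConfig(nTdTrain = 0L), "> 0")
  expect_error(smallConfig(rewardRegions = c(1:7, 99L)), "nRegions")
})
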