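#' @include AllClasses.R cohort.R utils.R
NULL

# default discriminative region sets: 14 reward-preferring cortical parcels
# plus bilateral caudate/putamen/accumbens (20 total), and 14
# punishment-preferring cortical parcels (insula-like), mirroring the
# 20 + 14 feature split the classifier is expected to recover
defaultRegionSets <- function(nRegions) {
  if (nRegions < 34L)
    stop("default region sets need nRegions >= 34; supply sets explicitly")
  if (nRegions > 12L + 28L) {
    nCort <- nRegions - 12L
    reward <- c(1:14, nCort + c(2L, 3L, 4L, 8L, 9L, 10L))
  } else {
    reward <- 1:20
  }
  list(reward = as.integer(reward), punishment = 15:28)
}

#' Create a synthetic-cohort configuration
#'
#' Supplies the study-sized defaults of the generative model: a TD training
#' sample of 65, an independent TD test sample of 39, a clinical sample of
#' 195; 412 regions (400 cortical parcels + 12 subcortical structures) of
#' which 20 are reward-preferring and 14 punishment-preferring; diagnosis
#' prevalences matching the clinical subgroup sizes (CD 105, ADHD 140,
#' MDD 35, GAD 63 of 195); reward-response gains attenuated per diagnosis;
#' and symptom scales coupled to (1 - gain) for the conduct/ADHD/
#' depression-related instruments.
#'
#' @param nTdTrain,nTdTest,nClinical group sizes.
#' @param nRegions number of regions (feature columns).
#' @param rewardRegions,punishmentRegions disjoint 1-based region indices;
#'   defaults derived from `nRegions` (20 reward, 14 punishment).
#' @param deltaReward,deltaPunishment effect magnitudes (response units).
#' @param subjectSd,noiseSd subject-effect and residual s.d.
#' @param attenuation named reward gain lambda in \[0,1\] per diagnosis.
#' @param diagnosisRates named marginal diagnosis-flag probabilities.
#' @param symptomBeta,symptomNoiseSd named per-scale coupling slopes and
#'   residual s.d.; partial named vectors override the defaults.
#' @param missingRate probability each scale score is missing.
#' @param confoundAge induce an age-group association plus an age-symptom
#'   slope (for exercising covariate-adjusted comparisons).
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nRegions = 60, seed = 7)
#' @export
simulationConfig <- function(nTdTrain = 65L, nTdTest = 39L, nClinical = 195L,
    nRegions = 412L, rewardRegions = NULL, punishmentRegions = NULL,
    deltaReward = 1.0, deltaPunishment = 1.0,
    subjectSd = 0.5, noiseSd = 1.0,
    attenuation = c(CD = 0.4, ADHD = 0.5, MDD = 0.6, GAD = 0.8),
    diagnosisRates = c(CD = 0.54, ADHD = 0.72, MDD = 0.18, GAD = 0.32),
    symptomBeta = NULL, symptomNoiseSd = NULL,
    missingRate = 0, confoundAge = FALSE, seed = 1L) {
  if (is.null(rewardRegions) || is.null(punishmentRegions)) {
    sets <- defaultRegionSets(as.integer(nRegions))
    if (is.null(rewardRegions)) rewardRegions <- sets$reward
    if (is.null(punishmentRegions)) punishmentRegions <- sets$punishment
  }
  defs <- scaleDefinitions()
  beta <- stats::setNames(defs$beta, rownames(defs))
  nsd <- stats::setNames(defs$noiseSd, rownames(defs))
  if (!is.null(symptomBeta)) {
    bad <- setdiff(names(symptomBeta), names(beta))
    if (length(bad)) stop("unknown scales in symptomBeta: ",
                          paste(bad, collapse = ", "))
    beta[names(symptomBeta)] <- symptomBeta
  }
  if (!is.null(symptomNoiseSd)) {
    bad <- setdiff(names(symptomNoiseSd), names(nsd))
    if (length(bad)) stop("unknown scales in symptomNoiseSd: ",
                          paste(bad, collapse = ", "))
    nsd[names(symptomNoiseSd)] <- symptomNoiseSd
  }
  methods::new("SimulationConfig",
    nTdTrain = as.integer(nTdTrain), nTdTest = as.integer(nTdTest),
    nClinical = as.integer(nClinical), nRegions = as.integer(nRegions),
    rewardRegions = as.integer(rewardRegions),
    punishmentRegions = as.integer(punishmentRegions),
    deltaReward = deltaReward, deltaPunishment = deltaPunishment,
    subjectSd = subjectSd, noiseSd = noiseSd,
    attenuation = attenuation[.DIAGNOSES],
    diagnosisRates = diagnosisRates[.DIAGNOSES],
    symptomBeta = beta, symptomNoiseSd = nsd,
    missingRate = missingRate, confoundAge = isTRUE(confoundAge),
    seed = as.integer(seed))
}

#' Simulate a cohort with known ground truth
#'
#' Generates a feature table and phenotype table under an additive model:
#' the response of subject s in condition c at region r is
#' `u_s + I(c == reward) * g_s * deltaReward_r +
#'  I(c == punishment) * deltaPunishment_r + eps`,
#' with `u_s ~ N(0, subjectSd)`, `eps ~ N(0, noiseSd)`, gain `g_s = 1` for
#' TD subjects and the minimum attenuation lambda over a clinical subject's
#' diagnoses. Punishment-condition responses are untouched by attenuation.
#' Symptom scales are affine in `(1 - g_s)` plus noise, truncated to each
#' instrument's range. Identical configuration (including seed) yields a
#' bit-identical cohort; randomness is consumed in a fixed order so cohorts
#' differing only in `attenuation` share all random draws.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return a [RewardCohort-class] with the realized ground truth (per-subject
#'   gains, per-region effect vectors) in `metadata(x)$groundTruth`.
#' @examples
#' cohort <- simulateCohort(simulationConfig(nRegions = 60, seed = 1))
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  nTr <- config@nTdTrain; nTe <- config@nTdTest; nCl <- config@nClinical
  n <- nTr + nTe + nCl
  nReg <- config@nRegions
  regions <- regionLabels(nReg)
  ids <- sprintf("sub%04d", seq_len(n))
  group <- factor(rep(.GROUPS, times = c(nTr, nTe, nCl)), levels = .GROUPS)
  clinical <- group == "clinical"

  deltaRew <- numeric(nReg); deltaRew[config@rewardRegions] <- config@deltaReward
  deltaPun <- numeric(nReg); deltaPun[config@punishmentRegions] <- config@deltaPunishment

  withSeed(config@seed, {
    # 1. diagnosis flags (clinical only); all-zero rows resampled so every
    #    clinical subject carries at least one diagnosis
    flags <- matrix(FALSE, n, 4L, dimnames = list(NULL, .DIAGNOSES))
    if (nCl > 0L) {
      draw <- matrix(stats::runif(nCl * 4L), nCl, 4L)
      f <- sweep(draw, 2L, config@diagnosisRates, "<")
      none <- which(rowSums(f) == 0L)
      while (length(none)) {
        redraw <- matrix(stats::runif(length(none) * 4L), length(none), 4L)
        f[none, ] <- sweep(redraw, 2L, config@diagnosisRates, "<")
        none <- none[rowSums(f[none, , drop = FALSE]) == 0L]
      }
      flags[clinical, ] <- f
    }
    # 2. gains: min lambda over the subject's diagnoses, 1 for TD
    g <- rep(1, n)
    if (nCl > 0L) {
      lam <- matrix(rep(config@attenuation, each = sum(clinical)),
                    ncol = 4L)
      lam[!flags[clinical, , drop = FALSE]] <- Inf
      g[clinical] <- pmin(1, apply(lam, 1L, min))
    }
    # 3. subject random effects, 4. residuals
    u <- stats::rnorm(n, 0, config@subjectSd)
    eps <- matrix(stats::rnorm(2L * n * nReg, 0, config@noiseSd),
                  nrow = 2L * n, ncol = nReg)
    # 5-7. demographics
    uAge <- stats::runif(n)
    age <- if (config@confoundAge)
      ifelse(clinical, 13 + 6 * uAge, 10 + 6 * uAge) else 10 + 9 * uAge
    femaleProp <- c(TD_train = 32 / 65, TD_test = 14 / 39,
                    clinical = 71 / 195)
    sex <- ifelse(stats::runif(n) < femaleProp[as.character(group)],
                  "F", "M")
    IQ <- stats::rnorm(n, 100, 12)
    # 8. symptom scales: affine in (1 - g) plus noise, truncated to range
    defs <- scaleDefinitions()
    coupled <- config@symptomBeta > 0
    scales <- matrix(NA_real_, n, nrow(defs),
                     dimnames = list(NULL, rownames(defs)))
    for (sc in rownames(defs)) {
      val <- defs[sc, "intercept"] +
        config@symptomBeta[[sc]] * (1 - g) +
        stats::rnorm(n, 0, config@symptomNoiseSd[[sc]])
      if (config@confoundAge && coupled[[sc]])
        val <- val + 0.6 * (age - 14.5)
      scales[, sc] <- pmin(pmax(val, defs[sc, "lo"]), defs[sc, "hi"])
    }
    # 9. optional missingness on scale scores
    if (config@missingRate > 0) {
      mask <- matrix(stats::runif(length(scales)) < config@missingRate,
                     nrow = n)
      scales[mask] <- NA_real_
    }

    # assemble features: per subject, a reward row then a punishment row
    condRow <- rep(.CONDITIONS, times = n)
    subjRow <- rep(seq_len(n), each = 2L)
    base <- u[subjRow] + eps
    isRew <- condRow == "reward"
    effect <- matrix(0, 2L * n, nReg)
    effect[isRew, ] <- outer(g[subjRow[isRew]], deltaRew)
    effect[!isRew, ] <- matrix(deltaPun, sum(!isRew), nReg, byrow = TRUE)
    bold <- base + effect
    colnames(bold) <- regions

    features <- data.frame(subject_id = ids[subjRow], condition = condRow,
                           bold, check.names = FALSE)
    phen <- data.frame(subject_id = ids, group = group, age = age,
                       sex = sex, IQ = IQ,
                       as.data.frame(flags), scales,
                       check.names = FALSE, stringsAsFactors = FALSE)
    truth <- list(
      g = stats::setNames(g, ids),
      deltaReward = stats::setNames(deltaRew, regions),
      deltaPunishment = stats::setNames(deltaPun, regions),
      rewardRegions = regions[config@rewardRegions],
      punishmentRegions = regions[config@punishmentRegions],
      seed = config@seed)
    rewardCohort(features, phen, groundTruth = truth)
  })
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@nTdTrain, "TD_train /", object@nTdTest, "TD_test /",
      object@nClinical, "clinical;",
      object@nRegions, "regions (",
      length(object@rewardRegions), "reward-preferring,",
      length(object@punishmentRegions), "punishment-preferring )\n")
  cat("  deltas:", object@deltaReward, "/", object@deltaPunishment,
      "; subjectSd:", object@subjectSd, "; noiseSd:", object@noiseSd,
      "; seed:", object@seed, "\n")
  cat("  attenuation:",
      paste(names(object@attenuation), object@attenuation,
            sep = "=", collapse = " "), "\n")
  invisible(NULL)
})
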