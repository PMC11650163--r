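#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# canonical vocabularies used throughout --------------------------------------

.CONDITIONS <- c("reward", "punishment")
.GROUPS <- c("TD_train", "TD_test", "clinical")
.DIAGNOSES <- c("CD", "ADHD", "MDD", "GAD")

# five s.d. categories, ordered low -> high so that contingency columns read
# from most deficient to most exaggerated
.CATEGORIES <- c("below_minus2", "minus2_to_minus1", "normative",
                 "plus1_to_plus2", "above_plus2")

#' Configuration of the synthetic cohort generator
#'
#' Holds every knob of the generative model used by [simulateCohort()]:
#' group sizes, the region sets carrying a reward>punishment or
#' punishment>reward contrast, effect magnitudes, noise levels, the
#' per-diagnosis attenuation of the reward response, diagnosis prevalence,
#' and the coupling of symptom-scale scores to reward-response integrity.
#' Construct with [simulationConfig()], which supplies study-sized defaults.
#'
#' @slot nTdTrain,nTdTest,nClinical group sizes (subjects).
#' @slot nRegions number of brain regions (feature columns).
#' @slot rewardRegions,punishmentRegions disjoint 1-based region indices
#'   carrying, respectively, a reward-preferring or punishment-preferring
#'   response.
#' @slot deltaReward,deltaPunishment per-region effect magnitude (response
#'   units) on those sets.
#' @slot subjectSd s.d. of the additive subject-level random effect.
#' @slot noiseSd s.d. of the i.i.d. residual per cell.
#' @slot attenuation named gain lambda in \[0,1\] per diagnosis; a clinical
#'   subject's reward-condition contrast is multiplied by the minimum lambda
#'   over their diagnoses.
#' @slot diagnosisRates named marginal probability per diagnosis flag;
#'   comorbidity arises from independent flags (all-zero draws resampled).
#' @slot symptomBeta named slope per clinical scale coupling the score to
#'   (1 - subject gain).
#' @slot symptomNoiseSd named residual s.d. per scale.
#' @slot missingRate probability a scale score is missing.
#' @slot confoundAge when TRUE, induces an age-group association and an
#'   age-symptom slope so covariate-adjusted comparisons can be exercised.
#' @slot seed integer RNG seed; identical seed gives bit-identical cohorts.
#' @export
setClass("SimulationConfig",
  representation(
    nTdTrain = "integer", nTdTest = "integer", nClinical = "integer",
    nRegions = "integer",
    rewardRegions = "integer", punishmentRegions = "integer",
    deltaReward = "numeric", deltaPunishment = "numeric",
    subjectSd = "numeric", noiseSd = "numeric",
    attenuation = "numeric", diagnosisRates = "numeric",
    symptomBeta = "numeric", symptomNoiseSd = "numeric",
    missingRate = "numeric", confoundAge = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(object@nTdTrain, object@nTdTest, object@nClinical,
              object@nRegions)
  if (any(counts <= 0L)) msg <- c(msg, "all counts must be > 0")
  rr <- object@rewardRegions; pr <- object@punishmentRegions
  if (length(intersect(rr, pr)))
    msg <- c(msg, "rewardRegions and punishmentRegions must be disjoint")
  if (length(rr) && (min(rr) < 1L || max(rr) > object@nRegions))
    msg <- c(msg, "rewardRegions out of [1, nRegions]")
  if (length(pr) && (min(pr) < 1L || max(pr) > object@nRegions))
    msg <- c(msg, "punishmentRegions out of [1, nRegions]")
  if (anyDuplicated(rr) || anyDuplicated(pr))
    msg <- c(msg, "region index sets must not contain duplicates")
  if (any(object@attenuation < 0) || any(object@attenuation > 1))
    msg <- c(msg, "attenuation gains must lie in [0, 1]")
  if (!setequal(names(object@attenuation), .DIAGNOSES))
    msg <- c(msg, "attenuation must be named for CD, ADHD, MDD, GAD")
  if (!setequal(names(object@diagnosisRates), .DIAGNOSES))
    msg <- c(msg, "diagnosisRates must be named for CD, ADHD, MDD, GAD")
  if (any(object@diagnosisRates < 0) || any(object@diagnosisRates > 1))
    msg <- c(msg, "diagnosisRates must lie in [0, 1]")
  if (object@subjectSd <= 0 || object@noiseSd <= 0)
    msg <- c(msg, "subjectSd and noiseSd must be > 0")
  if (any(object@symptomNoiseSd < 0))
    msg <- c(msg, "symptomNoiseSd must be >= 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Cohort container: BOLD features plus phenotypes
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"bold"`
#' (regions x observations) and two columns (observations) per subject, one
#' per outcome condition. `colData` carries `subject_id`, `condition`,
#' `group` and the per-subject phenotype columns (replicated across the
#' subject's two observations). Simulated cohorts additionally carry the
#' realized ground truth (per-subject gain, per-region effect vectors) in
#' `metadata(x)$groundTruth`.
#'
#' @export
setClass("RewardCohort", contains = "SummarizedExperiment")

setValidity("RewardCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  if (!all(c("subject_id", "condition") %in% colnames(cd)))
    return("colData must contain subject_id and condition")
  if (!"bold" %in% SummarizedExperiment::assayNames(object))
    return("assay 'bold' is required")
  cond <- as.character(cd$condition)
  if (!all(cond %in% .CONDITIONS))
    msg <- c(msg, "condition labels must be 'reward' or 'punishment'")
  tab <- table(cd$subject_id, factor(cond, levels = .CONDITIONS))
  bad <- rownames(tab)[rowSums(tab != 1L) > 0L]
  if (length(bad))
    msg <- c(msg, paste0("subjects without exactly one row per condition: ",
                         paste(utils::head(bad, 5L), collapse = ", ")))
  a <- SummarizedExperiment::assay(object, "bold")
  if (anyNA(a) || any(!is.finite(a)))
    msg <- c(msg, "assay 'bold' contains missing or non-finite values")
  if (length(msg)) msg else TRUE
})

#' Per-region standardization parameters
#'
#' Column means and standard deviations estimated from the training
#' observations only (both conditions pooled), applied to every later
#' observation so no information leaks from test or clinical rows.
#'
#' @slot center,scale named per-region mean and s.d.
#' @slot nObs number of training observations used.
#' @slot trainingSubjects the subject ids the parameters came from.
#' @export
setClass("Standardizer",
  representation(center = "numeric", scale = "numeric", nObs = "integer",
                 trainingSubjects = "character"))

setValidity("Standardizer", function(object) {
  if (length(object@center) != length(object@scale))
    return("center and scale lengths differ")
  if (any(object@scale <= 0)) return("all scale values must be > 0")
  if (is.null(names(object@center))) return("center must be named by region")
  TRUE
})

#' L1-selected discriminative regions
#'
#' Result of the penalized-logistic selection stage: the regions with
#' nonzero coefficient at the penalty chosen by subject-grouped
#' cross-validation (one-standard-error rule), with coefficient signs
#' (positive = reward-preferring).
#'
#' @slot regionIds selected region labels (possibly empty).
#' @slot signs named +1/-1 per selected region.
#' @slot lambda penalty chosen.
#' @slot lambdaGrid the fitted penalty path.
#' @slot folds,seed cross-validation metadata.
#' @slot empty TRUE when no grid point retained any feature.
#' @export
setClass("FeatureSelection",
  representation(regionIds = "character", signs = "integer",
                 lambda = "numeric", lambdaGrid = "numeric",
                 folds = "integer", seed = "integer", empty = "logical"))

setValidity("FeatureSelection", function(object) {
  if (length(object@signs) != length(object@regionIds))
    return("signs must be one per selected region")
  if (length(object@signs) && !all(object@signs %in% c(-1L, 1L)))
    return("signs must be +1 or -1")
  TRUE
})

setClassUnion("StandardizerOrNULL", c("Standardizer", "NULL"))
setClassUnion("FeatureSelectionOrNULL", c("FeatureSelection", "NULL"))

#' Linear decision hyperplane
#'
#' The max-margin boundary \{x : w.x + b = 0\} in standardized selected
#' feature space, oriented so reward-condition observations lie on the
#' positive side. Carries the Standardizer and FeatureSelection used to
#' map raw feature rows into its space.
#'
#' @slot weights named weight per selected region (standardized units).
#' @slot intercept scalar offset b.
#' @slot regionIds the selected regions, in weight order.
#' @slot standardizer,selection preprocessing provenance (may be NULL for
#'   hand-built hyperplanes).
#' @slot orientation fixed label `"reward_positive"`.
#' @slot cost soft-margin cost C used in fitting.
#' @export
setClass("Hyperplane",
  representation(weights = "numeric", intercept = "numeric",
                 regionIds = "character",
                 standardizer = "StandardizerOrNULL",
                 selection = "FeatureSelectionOrNULL",
                 orientation = "character", cost = "numeric"))

setValidity("Hyperplane", function(object) {
  if (length(object@weights) == 0L || sqrt(sum(object@weights^2)) <= 0)
    return("weight vector must be non-zero")
  if (length(object@weights) != length(object@regionIds))
    return("weights and regionIds lengths differ")
  if (!identical(object@orientation, "reward_positive"))
    return("orientation must be 'reward_positive'")
  TRUE
})

#' Norming reference for reward distances
#'
#' Mean and sample s.d. (ddof = 1) of the training sample's reward-condition
#' signed distances; all other subjects' reward distances are z-scored and
#' binned against it.
#'
#' @slot mu,sigma training mean and s.d.
#' @slot n number of training subjects contributing.
#' @export
setClass("NormReference",
  representation(mu = "numeric", sigma = "numeric", n = "integer"))

setValidity("NormReference", function(object) {
  if (object@n < 2L) return("need at least 2 training distances")
  if (!is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be > 0 (degenerate training distances)")
  TRUE
})

#' Subject-grouped cross-validation result
#'
#' Pooled held-out confusion counts and derived metrics for the condition
#' classifier, with reward as the positive class. Each subject's two
#' observations always share a fold.
#'
#' @slot confusion named integer counts TP, FP, TN, FN.
#' @slot accuracy,sensitivity,specificity pooled metrics.
#' @slot k,seed fold count and fold-assignment seed.
#' @slot foldSubjects list of subject-id vectors, one per fold.
#' @slot positiveClass `"reward"`.
#' @export
setClass("CVResult",
  representation(confusion = "integer", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 k = "integer", seed = "integer", foldSubjects = "list",
                 positiveClass = "character"))

setValidity("CVResult", function(object) {
  cf <- object@confusion
  if (!setequal(names(cf), c("TP", "FP", "TN", "FN")))
    return("confusion must be named TP, FP, TN, FN")
  if (any(cf < 0L)) return("confusion counts must be >= 0")
  tot <- sum(cf)
  if (tot > 0L) {
    acc <- (cf[["TP"]] + cf[["TN"]]) / tot
    if (abs(acc - object@accuracy) > 1e-12)
      return("accuracy inconsistent with confusion counts")
  }
  TRUE
})
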