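#' @include AllClasses.R select.R utils.R
NULL

#' Fit the linear max-margin condition classifier
#'
#' Soft-margin linear SVM minimizing `0.5 * ||w||^2 + C * sum(hinge)`,
#' fitted on standardized, selected training observations. The hyperplane
#' is re-oriented (w and b negated) if needed so that the mean signed
#' distance of reward-condition training observations is positive.
#'
#' @param x standardized selected observations-by-regions matrix.
#' @param condition label per row (`"reward"`/`"punishment"`); both must
#'   occur.
#' @param C soft-margin cost (> 0), default 1.
#' @param standardizer,selection optional provenance objects stored on the
#'   hyperplane so raw observations can be scored later.
#' @return a [Hyperplane-class].
#' @examples
#' x <- rbind(c(2, 0), c(-2, 0)); colnames(x) <- c("A", "B")
#' h <- fitHyperplane(x, c("reward", "punishment"), C = 1e6)
#' signedDistance(h, x)   # +2, -2
#' @export
fitHyperplane <- function(x, condition, C = 1, standardizer = NULL,
                          selection = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(condition), C > 0)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite features")
  condition <- as.character(condition)
  if (length(unique(condition)) < 2L)
    stop("both condition labels must be present")
  y <- factor(condition, levels = .CONDITIONS)
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  if (l2norm(w) == 0) stop("degenerate fit: zero weight vector")
  # orientation: reward side positive
  dRew <- (x[condition == "reward", , drop = FALSE] %*% w + b) / l2norm(w)
  if (mean(dRew) < 0) { w <- -w; b <- -b }
  methods::new("Hyperplane",
    weights = stats::setNames(as.numeric(w), colnames(x)),
    intercept = b, regionIds = colnames(x),
    standardizer = standardizer, selection = selection,
    orientation = "reward_positive", cost = C)
}

#' Train the full classifier stack on a training sample
#'
#' Convenience wrapper running the leakage-safe training pipeline on one
#' subject set: fit the standardizer, select features by grouped-CV
#' penalized logistic classification, and fit the max-margin hyperplane on
#' the standardized selected features.
#'
#' @param cohort a [RewardCohort-class].
#' @param trainingIds training subject ids; default the `TD_train` group.
#' @param C soft-margin cost.
#' @param folds selection cross-validation folds.
#' @param seed fold-assignment seed.
#' @param useSelection when FALSE, skip the L1 stage and fit on all regions.
#' @return a [Hyperplane-class] carrying its standardizer and selection.
#' @export
trainClassifier <- function(cohort, trainingIds = NULL, C = 1, folds = 10L,
                            seed = 1L, useSelection = TRUE) {
  if (is.null(trainingIds)) trainingIds <- groupSubjects(cohort, "TD_train")
  folds <- min(folds, length(trainingIds))
  std <- fitStandardizer(cohort, trainingIds)
  cd <- SummarizedExperiment::colData(cohort)
  keep <- cd$subject_id %in% trainingIds
  xs <- applyStandardizer(std, cohort, subjects = trainingIds)
  cond <- as.character(cd$condition[keep])
  subj <- cd$subject_id[keep]
  sel <- NULL
  if (useSelection) {
    sel <- selectFeatures(xs, cond, subj, folds = folds, seed = seed)
    if (sel@empty) {
      warning("empty selection; falling back to all regions")
      sel <- NULL
    }
  }
  xsel <- if (is.null(sel)) xs else xs[, sel@regionIds, drop = FALSE]
  fitHyperplane(xsel, cond, C = C, standardizer = std, selection = sel)
}

#' Subject-grouped cross-validated evaluation of the classifier
#'
#' k-fold cross-validation grouped by subject: each subject's reward and
#' punishment observations share a fold, and the standardizer, feature
#' selection and hyperplane are refit within every fold's training split.
#' Held-out confusion counts are pooled; reward is the positive class.
#'
#' @param cohort a [RewardCohort-class].
#' @param trainingIds subject ids to evaluate over; default `TD_train`.
#' @param k folds (>= 2), default 10.
#' @param C soft-margin cost.
#' @param seed fold-assignment seed.
#' @param useSelection refit the L1 selection inside each fold (default);
#'   when a fold's selection is empty, that fold falls back to all regions.
#' @param selectionFolds inner folds for the per-fold selection.
#' @return a [CVResult-class].
#' @export
groupedCvEvaluate <- function(cohort, trainingIds = NULL, k = 10L, C = 1,
                              seed = 1L, useSelection = TRUE,
                              selectionFolds = 10L) {
  if (is.null(trainingIds)) trainingIds <- groupSubjects(cohort, "TD_train")
  trainingIds <- sort(unique(as.character(trainingIds)))
  if (length(trainingIds) < k) stop("fewer subjects than folds")
  foldOf <- withSeed(seed, {
    perm <- sample(trainingIds)
    stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  })
  cd <- SummarizedExperiment::colData(cohort)
  confusion <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  foldSubjects <- vector("list", k)
  for (f in seq_len(k)) {
    testIds <- names(foldOf)[foldOf == f]
    trainIds <- setdiff(trainingIds, testIds)
    foldSubjects[[f]] <- sort(testIds)
    std <- fitStandardizer(cohort, trainIds)
    keepTr <- cd$subject_id %in% trainIds
    xs <- applyStandardizer(std, cohort, subjects = trainIds)
    cond <- as.character(cd$condition[keepTr])
    subj <- cd$subject_id[keepTr]
    sel <- NULL
    if (useSelection) {
      sel <- suppressWarnings(
        selectFeatures(xs, cond, subj,
                       folds = min(selectionFolds, length(trainIds)),
                       seed = seed))
      if (sel@empty) sel <- NULL
    }
    xsel <- if (is.null(sel)) xs else xs[, sel@regionIds, drop = FALSE]
    h <- fitHyperplane(xsel, cond, C = C)
    xTest <- applyStandardizer(std, cohort, subjects = testIds)
    d <- signedDistance(h, xTest[, h@regionIds, drop = FALSE])
    truth <- as.character(cd$condition[cd$subject_id %in% testIds])
    predRew <- d > 0
    confusion["TP"] <- confusion["TP"] + sum(predRew & truth == "reward")
    confusion["FN"] <- confusion["FN"] + sum(!predRew & truth == "reward")
    confusion["TN"] <- confusion["TN"] + sum(!predRew & truth == "punishment")
    confusion["FP"] <- confusion["FP"] + sum(predRew & truth == "punishment")
  }
  cvResult(confusion, k = k, seed = seed, foldSubjects = foldSubjects)
}

# assemble a CVResult from confusion counts (exported for definitional use)

#' Build a cross-validation result from confusion counts
#'
#' @param confusion named integer vector TP, FP, TN, FN (reward positive).
#' @param k,seed,foldSubjects fold metadata.
#' @return a [CVResult-class] with accuracy, sensitivity, specificity.
#' @examples
#' cvResult(c(TP = 9L, FN = 1L, TN = 8L, FP = 2L))
#' @export
cvResult <- function(confusion, k = NA_integer_, seed = NA_integer_,
                     foldSubjects = list()) {
  confusion <- as.integer(confusion[c("TP", "FP", "TN", "FN")])
  names(confusion) <- c("TP", "FP", "TN", "FN")
  methods::new("CVResult", confusion = confusion,
    accuracy = (confusion[["TP"]] + confusion[["TN"]]) / sum(confusion),
    sensitivity = confusion[["TP"]] /
      (confusion[["TP"]] + confusion[["FN"]]),
    specificity = confusion[["TN"]] /
      (confusion[["TN"]] + confusion[["FP"]]),
    k = as.integer(k), seed = as.integer(seed),
    foldSubjects = foldSubjects, positiveClass = "reward")
}

#' @rdname accessors
#' @export
setMethod("regionIds", "Hyperplane", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("intercept", "Hyperplane", function(x) x@intercept)

#' @importFrom stats weights
#' @export
setMethod("weights", "Hyperplane", function(object, ...)
  stats::setNames(object@weights, object@regionIds))

setMethod("show", "Hyperplane", function(object) {
  cat("Hyperplane:", length(object@weights), "regions; ||w|| =",
      signif(l2norm(object@weights), 5), "; b =",
      signif(object@intercept, 5), "; reward side positive\n")
  invisible(NULL)
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult (%d-fold, grouped by subject, positive = %s)\n",
    object@k, object@positiveClass))
  print(object@confusion)
  cat(sprintf("accuracy %.4f  sensitivity %.4f  specificity %.4f\n",
              object@accuracy, object@sensitivity, object@specificity))
  invisible(NULL)
})
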