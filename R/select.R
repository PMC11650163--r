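#' @include AllClasses.R standardize.R utils.R
NULL

# subject-grouped fold assignment: subjects shuffled then dealt round-robin,
# so each subject's reward and punishment rows always share a fold
groupedFoldIds <- function(subjects, k, seed) {
  uniq <- unique(subjects)
  if (k < 2L) stop("need k >= 2 folds")
  if (length(uniq) < k) stop("fewer subjects than folds")
  perm <- withSeed(seed, sample(uniq))
  foldOfSubject <- stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  foldOfSubject[as.character(subjects)]
}

#' Select discriminative regions by L1-penalized logistic classification
#'
#' Fits an L1-penalized logistic model of condition (reward = 1) on
#' standardized features over a log-spaced penalty path, chooses the penalty
#' by subject-grouped cross-validated deviance under the one-standard-error
#' rule, and returns the regions with nonzero coefficient there. Positive
#' coefficients mark reward-preferring regions, negative ones
#' punishment-preferring.
#'
#' @param x standardized observations-by-regions matrix (training rows only).
#' @param condition condition label per row (`"reward"`/`"punishment"`).
#' @param subject subject id per row (used for grouped folds).
#' @param folds number of cross-validation folds (default 10).
#' @param nLambda length of the automatic penalty path (default 50).
#' @param lambdaGrid optional explicit penalty values (decreasing).
#' @param seed seed for the fold assignment.
#' @return a [FeatureSelection-class]; empty (with a warning) when no grid
#'   point retains any feature.
#' @export
selectFeatures <- function(x, condition, subject, folds = 10L,
                           nLambda = 50L, lambdaGrid = NULL, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(condition),
            nrow(x) == length(subject))
  condition <- as.character(condition)
  if (!all(condition %in% .CONDITIONS))
    stop("condition labels must be 'reward' or 'punishment'")
  if (length(unique(condition)) < 2L)
    stop("both conditions must be present")
  y <- as.integer(condition == "reward")

  if (!is.null(lambdaGrid) && length(lambdaGrid) == 1L) {
    # degenerate single-penalty grid: no CV possible, fit directly
    fit <- glmnet::glmnet(x, y, family = "binomial",
                          lambda = lambdaGrid, standardize = FALSE)
    cf <- as.matrix(stats::coef(fit))[-1L, 1L]
    chosen <- lambdaGrid
    grid <- lambdaGrid
  } else {
    foldid <- groupedFoldIds(subject, folds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                            type.measure = "deviance", foldid = foldid,
                            lambda = lambdaGrid, nlambda = nLambda,
                            standardize = FALSE)
    chosen <- cv$lambda.1se
    grid <- cv$lambda
    cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1L, 1L]
    if (all(cv$nzero == 0L))
      warning("no feature retained at any penalty: no separable signal")
    if (length(grid) < nLambda / 2)
      warning("penalty grid terminated early (", length(grid),
              " of ", nLambda, " values); grid may be too coarse")
  }
  nz <- which(cf != 0)
  if (!length(nz))
    warning("empty feature selection at the chosen penalty")
  methods::new("FeatureSelection",
    regionIds = colnames(x)[nz],
    signs = as.integer(sign(cf[nz])),
    lambda = as.numeric(chosen), lambdaGrid = as.numeric(grid),
    folds = as.integer(folds), seed = as.integer(seed),
    empty = length(nz) == 0L)
}

#' @rdname accessors
#' @export
setMethod("regionIds", "FeatureSelection", function(x) x@regionIds)

#' Coefficient signs of the selected regions
#'
#' @param selection a [FeatureSelection-class].
#' @return named integer vector, +1 reward-preferring, -1
#'   punishment-preferring.
#' @export
selectionSigns <- function(selection) {
  stats::setNames(selection@signs, selection@regionIds)
}

setMethod("show", "FeatureSelection", function(object) {
  s <- selectionSigns(object)
  cat("FeatureSelection:", length(object@regionIds), "regions (",
      sum(s > 0), "reward-preferring,", sum(s < 0),
      "punishment-preferring ) at lambda =",
      signif(object@lambda, 4), "\n")
  invisible(NULL)
})
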