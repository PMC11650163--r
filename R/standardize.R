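#' @include AllClasses.R cohort.R
NULL

#' Fit per-region standardization on the training sample
#'
#' Estimates each region's mean and sample s.d. from the training subjects'
#' observations only, both conditions pooled (2 observations per subject),
#' so the classifier sees condition differences rather than having them
#' removed by per-condition scaling, and no information leaks from test or
#' clinical rows.
#'
#' @param cohort a [RewardCohort-class].
#' @param trainingIds subject ids defining the training sample (>= 2).
#' @return a [Standardizer-class].
#' @export
fitStandardizer <- function(cohort, trainingIds) {
  stopifnot(methods::is(cohort, "RewardCohort"))
  trainingIds <- unique(as.character(trainingIds))
  if (length(trainingIds) < 2L) stop("need >= 2 training subjects")
  missing <- setdiff(trainingIds, subjectIds(cohort))
  if (length(missing))
    stop("training subjects absent from cohort: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- obsMatrix(cohort, trainingIds)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  const <- colnames(x)[scl == 0 | !is.finite(scl)]
  if (length(const))
    stop("constant training column(s): ",
         paste(utils::head(const, 5L), collapse = ", "))
  methods::new("Standardizer", center = ctr, scale = scl,
               nObs = nrow(x), trainingSubjects = trainingIds)
}

#' Apply a standardizer to observations
#'
#' @param standardizer a [Standardizer-class].
#' @param x a [RewardCohort-class] or an observations-by-regions matrix with
#'   region column names.
#' @param subjects optional subject filter when `x` is a cohort.
#' @return standardized observations-by-regions matrix.
#' @export
applyStandardizer <- function(standardizer, x, subjects = NULL) {
  stopifnot(methods::is(standardizer, "Standardizer"))
  if (methods::is(x, "RewardCohort")) x <- obsMatrix(x, subjects)
  regions <- names(standardizer@center)
  missing <- setdiff(regions, colnames(x))
  if (length(missing))
    stop("observations lack region(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- x[, regions, drop = FALSE]
  scale(x, center = standardizer@center, scale = standardizer@scale)[, ,
    drop = FALSE]
}

setMethod("show", "Standardizer", function(object) {
  cat("Standardizer:", length(object@center), "regions from",
      length(object@trainingSubjects), "training subjects (",
      object@nObs, "observations )\n")
  invisible(NULL)
})
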