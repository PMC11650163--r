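#' @include AllClasses.R AllGenerics.R
NULL

#' Build a cohort object from feature and phenotype tables
#'
#' Assembles a validated [RewardCohort-class] from a long feature table (one
#' row per subject x condition, region columns) and an optional per-subject
#' phenotype table, as read by [readFeatureTable()] / [readPhenotypeTable()].
#'
#' @param features data.frame with columns `subject_id`, `condition`, then
#'   one numeric column per region.
#' @param phenotypes optional data.frame keyed by `subject_id`; every feature
#'   subject must be present.
#' @param groundTruth optional list stashed in `metadata()` (simulated
#'   cohorts store per-subject gains and per-region effects here).
#' @return a [RewardCohort-class].
#' @examples
#' ft <- data.frame(subject_id = rep(c("a", "b"), each = 2),
#'                  condition = rep(c("reward", "punishment"), 2),
#'                  R1 = rnorm(4), R2 = rnorm(4))
#' rewardCohort(ft)
#' @export
rewardCohort <- function(features, phenotypes = NULL, groundTruth = NULL) {
  stopifnot(is.data.frame(features))
  if (!all(c("subject_id", "condition") %in% colnames(features)))
    stop("features must have subject_id and condition columns")
  regionCols <- setdiff(colnames(features), c("subject_id", "condition"))
  if (!length(regionCols)) stop("features has no region columns")
  mat <- t(as.matrix(features[, regionCols, drop = FALSE]))
  obsNames <- paste(features$subject_id, features$condition, sep = ".")
  dimnames(mat) <- list(regionCols, obsNames)
  cd <- S4Vectors::DataFrame(
    subject_id = as.character(features$subject_id),
    condition = factor(as.character(features$condition),
                       levels = .CONDITIONS),
    row.names = obsNames)
  if (!is.null(phenotypes)) {
    stopifnot(is.data.frame(phenotypes))
    if (anyDuplicated(phenotypes$subject_id))
      stop("duplicate subject_id in phenotypes")
    missing <- setdiff(cd$subject_id, phenotypes$subject_id)
    if (length(missing))
      stop("phenotypes missing subjects: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    idx <- match(cd$subject_id, phenotypes$subject_id)
    ph <- phenotypes[idx, setdiff(colnames(phenotypes), "subject_id"),
                     drop = FALSE]
    rownames(ph) <- NULL
    cd <- cbind(cd, S4Vectors::DataFrame(ph))
  }
  rd <- S4Vectors::DataFrame(
    region_id = regionCols,
    region_type = ifelse(grepl("^Parcel_", regionCols),
                         "cortical", "subcortical"),
    row.names = regionCols)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bold = mat), colData = cd, rowData = rd,
    metadata = if (is.null(groundTruth)) list() else
      list(groundTruth = groundTruth))
  methods::new("RewardCohort", se)
}

#' @rdname accessors
#' @export
setMethod("subjectIds", "RewardCohort", function(x)
  unique(SummarizedExperiment::colData(x)$subject_id))

#' @rdname accessors
#' @export
setMethod("regionIds", "RewardCohort", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("conditions", "RewardCohort", function(x)
  SummarizedExperiment::colData(x)$condition)

#' @rdname accessors
#' @export
setMethod("groundTruth", "RewardCohort", function(x)
  S4Vectors::metadata(x)$groundTruth)

#' @rdname accessors
#' @export
setMethod("phenotypes", "RewardCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  keep <- !duplicated(cd$subject_id)
  out <- cd[keep, setdiff(colnames(cd), "condition"), drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @rdname accessors
#' @export
setMethod("featureTable", "RewardCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  out <- data.frame(subject_id = cd$subject_id,
                    condition = as.character(cd$condition),
                    t(SummarizedExperiment::assay(x, "bold")),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
})

# observations x regions matrix for given subjects (both conditions)
obsMatrix <- function(cohort, subjects = NULL) {
  cd <- SummarizedExperiment::colData(cohort)
  keep <- if (is.null(subjects)) rep(TRUE, ncol(cohort)) else
    cd$subject_id %in% subjects
  t(SummarizedExperiment::assay(cohort, "bold")[, keep, drop = FALSE])
}

# subject ids belonging to a named group
groupSubjects <- function(cohort, group) {
  ph <- phenotypes(cohort)
  if (!"group" %in% colnames(ph)) stop("cohort has no group phenotype")
  ph$subject_id[ph$group %in% group]
}

setMethod("show", "RewardCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("RewardCohort:", nrow(object), "regions x", ncol(object),
      "observations (", length(unique(cd$subject_id)), "subjects )\n")
  if ("group" %in% colnames(cd))
    print(table(cd$group[!duplicated(cd$subject_id)]))
  invisible(NULL)
})
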