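#' @include AllClasses.R
NULL

#' Accessors for cohort and model objects
#'
#' Small accessor generics following Bioconductor conventions: prefer these
#' over direct slot access.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' Signed distance from the hyperplane
#'
#' @param hyperplane a [Hyperplane-class].
#' @param x observations to score (see methods).
#' @param ... passed to methods.
#' @export
setGeneric("signedDistance",
           function(hyperplane, x, ...) standardGeneric("signedDistance"))
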