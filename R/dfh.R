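#' @include AllClasses.R AllGenerics.R classifier.R
NULL

#' @describeIn signedDistance distance of rows of a standardized selected
#'   feature matrix (or a single vector): `d = (w.x + b) / ||w||`, positive
#'   on the reward side.
#' @export
setMethod("signedDistance", signature("Hyperplane", "matrix"),
  function(hyperplane, x, ...) {
    w <- hyperplane@weights
    if (ncol(x) != length(w)) stop("dimension mismatch: expected ",
                                   length(w), " features, got ", ncol(x))
    if (anyNA(x) || any(!is.finite(x))) stop("non-finite features")
    drop(x %*% w + hyperplane@intercept) / l2norm(w)
  })

#' @describeIn signedDistance distance of a single numeric feature vector.
#' @export
setMethod("signedDistance", signature("Hyperplane", "numeric"),
  function(hyperplane, x, ...)
    signedDistance(hyperplane, matrix(x, nrow = 1L,
                                      dimnames = list(NULL, names(x)))))

#' @describeIn signedDistance distance of every observation of a cohort;
#'   raw features are standardized and subset to the selected regions using
#'   the hyperplane's stored preprocessing.
#' @export
setMethod("signedDistance", signature("Hyperplane", "RewardCohort"),
  function(hyperplane, x, ...) {
    if (is.null(hyperplane@standardizer))
      stop("hyperplane carries no standardizer; score a matrix instead")
    xs <- applyStandardizer(hyperplane@standardizer, x)
    signedDistance(hyperplane, xs[, hyperplane@regionIds, drop = FALSE])
  })

#' Build the norming reference from training reward distances
#'
#' @param distances signed distances of the training sample's
#'   reward-condition observations (>= 2, not all equal).
#' @return a [NormReference-class] with mean, sample s.d. (ddof = 1) and n.
#' @examples
#' buildNormReference(c(1, 2, 3))   # mu 2, sigma 1, n 3
#' @export
buildNormReference <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) < 2L) stop("need >= 2 training distances")
  if (anyNA(distances) || any(!is.finite(distances)))
    stop("non-finite training distances")
  sigma <- stats::sd(distances)
  if (sigma == 0) stop("degenerate training distances (all equal)")
  methods::new("NormReference", mu = mean(distances), sigma = sigma,
               n = length(distances))
}

#' Norm a distance against the training reference
#'
#' @param reference a [NormReference-class].
#' @param d signed distance(s).
#' @return z-score(s) `(d - mu) / sigma`.
#' @export
normDistance <- function(reference, d) {
  stopifnot(methods::is(reference, "NormReference"))
  (d - reference@mu) / reference@sigma
}

#' Assign the five s.d. categories
#'
#' Bins a normed reward distance into the five training-s.d. categories:
#' `> 2`, `1 to 2`, `-1 to 1` (normative), `-1 to -2`, `< -2`. Boundary
#' values are assigned to the inner (more normative) bin, so z = 1 and
#' z = -1 are normative and z = 2 / z = -2 fall in the 1-to-2 bands.
#'
#' @param z finite normed distance(s).
#' @return factor with levels `below_minus2`, `minus2_to_minus1`,
#'   `normative`, `plus1_to_plus2`, `above_plus2` (ordered low to high).
#' @examples
#' categorizeZ(c(-2.5, -1.5, 0, 1, 2.4))
#' @export
categorizeZ <- function(z) {
  if (any(!is.finite(z)))
    stop("non-finite z")
  out <- ifelse(z > 2, "above_plus2",
    ifelse(z > 1, "plus1_to_plus2",
      ifelse(z >= -1, "normative",
        ifelse(z >= -2, "minus2_to_minus1", "below_minus2"))))
  factor(out, levels = .CATEGORIES)
}

#' Score a cohort: distances, normed z and categories
#'
#' Computes each observation's signed distance from the hyperplane, norms
#' reward-condition distances against the training reference and assigns
#' the five s.d. categories. Punishment-condition rows receive a distance
#' only (reported both signed and as `d_pun = -d`, so that larger values
#' mean a stronger punishment-side response); categories apply to the
#' reward condition alone.
#'
#' @param cohort a [RewardCohort-class].
#' @param hyperplane a [Hyperplane-class] with stored preprocessing.
#' @param reference a [NormReference-class]; when NULL it is built from the
#'   cohort's `TD_train` reward distances.
#' @return data.frame of DFH records: `subject_id`, `condition`, `group`
#'   (when present), `d`, `d_pun`, `z`, `category`; the reference used is
#'   attached as `attr(, "reference")`.
#' @export
scoreCohort <- function(cohort, hyperplane, reference = NULL) {
  cd <- SummarizedExperiment::colData(cohort)
  d <- signedDistance(hyperplane, cohort)
  rec <- data.frame(subject_id = cd$subject_id,
                    condition = as.character(cd$condition),
                    stringsAsFactors = FALSE)
  if ("group" %in% colnames(cd)) rec$group <- as.character(cd$group)
  rec$d <- as.numeric(d)
  rec$d_pun <- ifelse(rec$condition == "punishment", -rec$d, NA_real_)
  if (is.null(reference)) {
    if (!"group" %in% colnames(cd))
      stop("no reference given and cohort has no group phenotype")
    trainRew <- rec$d[rec$group == "TD_train" & rec$condition == "reward"]
    if (!length(trainRew)) stop("cohort has no TD_train reward rows")
    reference <- buildNormReference(trainRew)
  }
  rec$z <- ifelse(rec$condition == "reward",
                  normDistance(reference, rec$d), NA_real_)
  rec$category <- factor(NA_character_, levels = .CATEGORIES)
  isRew <- rec$condition == "reward"
  rec$category[isRew] <- categorizeZ(rec$z[isRew])
  rownames(rec) <- NULL
  attr(rec, "reference") <- reference
  rec
}

setMethod("show", "NormReference", function(object) {
  cat(sprintf("NormReference: mu = %.5g, sigma = %.5g (n = %d)\n",
              object@mu, object@sigma, object@n))
  invisible(NULL)
})
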