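#' @include AllClasses.R cohort.R utils.R
NULL

readDelimAuto <- function(path) {
  # TSV canonical; CSV accepted on read
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read and validate a feature table
#'
#' Reads a TSV (or CSV) with columns `subject_id`, `condition`, then one
#' numeric column per region, and enforces the feature-table contract:
#' exactly one reward and one punishment row per subject, no missing cells,
#' a fixed column set. Unknown extra region columns (relative to
#' `regionIds`, when given) are kept with a warning.
#'
#' @param path file path.
#' @param regionIds optional expected region labels.
#' @return validated data.frame (long feature table).
#' @export
readFeatureTable <- function(path, regionIds = NULL) {
  df <- readDelimAuto(path)
  if (!all(c("subject_id", "condition") %in% colnames(df)[1:2]))
    stop("first two columns must be subject_id and condition")
  regionCols <- setdiff(colnames(df), c("subject_id", "condition"))
  if (!length(regionCols)) stop("no region columns found")
  bad <- regionCols[!vapply(df[regionCols], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric region columns: ", paste(bad, collapse = ", "))
  unknown <- df$condition[!df$condition %in% .CONDITIONS]
  if (length(unknown))
    stop("unknown condition label(s): ",
         paste(unique(unknown), collapse = ", "))
  if (anyNA(df[regionCols]))
    stop("feature table contains missing cells")
  key <- paste(df$subject_id, df$condition)
  if (anyDuplicated(key))
    stop("duplicate (subject, condition) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  tab <- table(df$subject_id, factor(df$condition, levels = .CONDITIONS))
  incomplete <- rownames(tab)[rowSums(tab) != 2L]
  if (length(incomplete))
    stop("subject(s) missing a condition row: ",
         paste(incomplete, collapse = ", "))
  if (!is.null(regionIds)) {
    extra <- setdiff(regionCols, regionIds)
    missing <- setdiff(regionIds, regionCols)
    if (length(missing))
      stop("expected region columns absent: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    if (length(extra))
      warning("unexpected region columns kept: ",
              paste(utils::head(extra, 5L), collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Read and validate a phenotype table
#'
#' Reads the per-subject phenotype table (group, demographics, diagnosis
#' flags, clinical scale scores). Missing scale values are permitted and
#' propagated; values outside the instrument's range are kept with a
#' warning.
#'
#' @param path file path.
#' @return validated data.frame keyed by unique `subject_id`.
#' @export
readPhenotypeTable <- function(path) {
  df <- readDelimAuto(path)
  if (!"subject_id" %in% colnames(df))
    stop("phenotype table must have a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if ("group" %in% colnames(df)) {
    bad <- setdiff(unique(df$group), .GROUPS)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
    df$group <- factor(df$group, levels = .GROUPS)
  }
  for (dx in .DIAGNOSES)
    if (dx %in% colnames(df)) df[[dx]] <- as.logical(df[[dx]])
  defs <- scaleDefinitions()
  for (v in intersect(c("age", "IQ", rownames(defs)), colnames(df)))
    df[[v]] <- as.double(df[[v]])
  for (sc in intersect(rownames(defs), colnames(df))) {
    v <- df[[sc]]
    out <- which(!is.na(v) & (v < defs[sc, "lo"] | v > defs[sc, "hi"]))
    if (length(out))
      warning(sprintf("%s: %d value(s) outside [%g, %g] kept",
                      sc, length(out), defs[sc, "lo"], defs[sc, "hi"]))
  }
  df
}

#' Write cohort tables to disk
#'
#' Writes `features.tsv`, `phenotypes.tsv` and, for simulated cohorts, the
#' realized ground truth as `ground_truth.json`. Doubles are written at full
#' precision so that a read back reproduces the cohort exactly.
#'
#' @param cohort a [RewardCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(features = file.path(dir, "features.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  writeTsv(featureTable(cohort), paths[["features"]])
  ph <- phenotypes(cohort)
  ph$group <- as.character(ph$group)
  writeTsv(ph, paths[["phenotypes"]])
  gt <- groundTruth(cohort)
  if (!is.null(gt)) {
    paths <- c(paths, ground_truth = file.path(dir, "ground_truth.json"))
    out <- gt
    for (nm in c("g", "deltaReward", "deltaPunishment"))
      out[[nm]] <- as.list(out[[nm]])   # keep names in the JSON object
    jsonlite::write_json(out, paths[["ground_truth"]], digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(paths)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `features.tsv` and `phenotypes.tsv`.
#' @return a [RewardCohort-class].
#' @export
readCohort <- function(dir) {
  feat <- readFeatureTable(file.path(dir, "features.tsv"))
  phen <- readPhenotypeTable(file.path(dir, "phenotypes.tsv"))
  gtPath <- file.path(dir, "ground_truth.json")
  gt <- NULL
  if (file.exists(gtPath)) {
    gt <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    gt$g <- unlist(gt$g)
    gt$deltaReward <- unlist(gt$deltaReward)
    gt$deltaPunishment <- unlist(gt$deltaPunishment)
  }
  rewardCohort(feat, phen, groundTruth = gt)
}

# --- JSON serialization of model objects -------------------------------------

hyperplaneToList <- function(h) {
  list(weights = as.list(stats::setNames(h@weights, h@regionIds)),
       intercept = h@intercept, region_ids = h@regionIds,
       orientation = h@orientation, cost = h@cost,
       standardizer = if (is.null(h@standardizer)) NULL else list(
         center = as.list(h@standardizer@center),
         scale = as.list(h@standardizer@scale),
         n_obs = h@standardizer@nObs,
         training_subjects = h@standardizer@trainingSubjects),
       selection = if (is.null(h@selection)) NULL else list(
         region_ids = h@selection@regionIds,
         signs = as.list(stats::setNames(h@selection@signs,
                                         h@selection@regionIds)),
         lambda = h@selection@lambda,
         lambda_grid = h@selection@lambdaGrid,
         folds = h@selection@folds, seed = h@selection@seed,
         empty = h@selection@empty))
}

hyperplaneFromList <- function(x) {
  std <- NULL
  if (!is.null(x$standardizer))
    std <- methods::new("Standardizer",
      center = unlist(x$standardizer$center),
      scale = unlist(x$standardizer$scale),
      nObs = as.integer(x$standardizer$n_obs),
      trainingSubjects = as.character(x$standardizer$training_subjects))
  sel <- NULL
  if (!is.null(x$selection))
    sel <- methods::new("FeatureSelection",
      regionIds = as.character(x$selection$region_ids),
      signs = as.integer(unlist(x$selection$signs)),
      lambda = as.numeric(x$selection$lambda),
      lambdaGrid = as.numeric(unlist(x$selection$lambda_grid)),
      folds = as.integer(x$selection$folds),
      seed = as.integer(x$selection$seed),
      empty = isTRUE(x$selection$empty))
  methods::new("Hyperplane",
    weights = unlist(x$weights), intercept = as.numeric(x$intercept),
    regionIds = as.character(x$region_ids), standardizer = std,
    selection = sel, orientation = x$orientation,
    cost = as.numeric(x$cost))
}

#' Write a results bundle as JSON files
#'
#' Serializes the model objects and statistical outputs of a run into a
#' directory of JSON files with deterministic key order: `hyperplane.json`,
#' `norm_reference.json`, `dfh.tsv` (per-subject records), and
#' `statistics.json` (every test/correlation/comparison result).
#'
#' @param bundle named list; recognized elements `hyperplane`
#'   ([Hyperplane-class]), `normReference` ([NormReference-class]), `dfh`
#'   (data.frame of DFH records), `statistics` (list or data.frame).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeResultsBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(bundle$hyperplane)) {
    p <- file.path(dir, "hyperplane.json")
    jsonlite::write_json(hyperplaneToList(bundle$hyperplane), p,
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, hyperplane = p)
  }
  if (!is.null(bundle$normReference)) {
    p <- file.path(dir, "norm_reference.json")
    r <- bundle$normReference
    jsonlite::write_json(list(mu = r@mu, sigma = r@sigma, n = r@n), p,
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, norm_reference = p)
  }
  if (!is.null(bundle$dfh)) {
    p <- file.path(dir, "dfh.tsv")
    writeTsv(bundle$dfh, p)
    paths <- c(paths, dfh = p)
  }
  if (!is.null(bundle$statistics)) {
    p <- file.path(dir, "statistics.json")
    jsonlite::write_json(bundle$statistics, p, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    paths <- c(paths, statistics = p)
  }
  invisible(paths)
}

#' Read a results bundle written by [writeResultsBundle()]
#'
#' @param dir directory of JSON files.
#' @return named list with the elements present on disk.
#' @export
readResultsBundle <- function(dir) {
  out <- list()
  p <- file.path(dir, "hyperplane.json")
  if (file.exists(p))
    out$hyperplane <- hyperplaneFromList(
      jsonlite::read_json(p, simplifyVector = TRUE))
  p <- file.path(dir, "norm_reference.json")
  if (file.exists(p)) {
    x <- jsonlite::read_json(p, simplifyVector = TRUE)
    out$normReference <- methods::new("NormReference", mu = x$mu,
                                      sigma = x$sigma, n = as.integer(x$n))
  }
  p <- file.path(dir, "dfh.tsv")
  if (file.exists(p)) {
    dfh <- readDelimAuto(p)
    dfh$subject_id <- as.character(dfh$subject_id)
    out$dfh <- dfh
  }
  p <- file.path(dir, "statistics.json")
  if (file.exists(p))
    out$statistics <- jsonlite::read_json(p, simplifyVector = TRUE)
  out
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain a `simulate` block (fields of [simulationConfig()])
#' and an `analysis` block (`folds`, `cost`, `seed`).
#'
#' @param path YAML or JSON configuration file.
#' @return list with elements `simulate` (a [SimulationConfig-class] or
#'   NULL), `features`/`phenotypes` paths (or NULL), and `analysis` options.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
    simplifyVector = TRUE) else yaml::read_yaml(path)
  cfg <- list(simulate = NULL, features = raw$features,
              phenotypes = raw$phenotypes,
              analysis = if (is.null(raw$analysis)) list() else raw$analysis)
  if (!is.null(raw$simulate)) {
    args <- raw$simulate
    for (nm in c("attenuation", "diagnosisRates", "symptomBeta",
                 "symptomNoiseSd"))
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    cfg$simulate <- do.call(simulationConfig, args)
  }
  if (is.null(cfg$simulate) &&
      (is.null(cfg$features) || is.null(cfg$phenotypes)))
    stop("config needs either a 'simulate' block or both 'features' and ",
         "'phenotypes' paths")
  cfg
}
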