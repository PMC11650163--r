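#' @include AllClasses.R simulate.R io.R classifier.R dfh.R stats.R
NULL

#' Run the full analysis pipeline
#'
#' Orchestrates the whole study analogue as one reproducible run:
#' simulate (or load) a cohort, select features and train the classifier on
#' the TD training sample, cross-validate it, score every subject's
#' distance from the hyperplane, norm and categorize reward distances, and
#' compute the downstream statistics (category contingency tests, DFH
#' correlations, typical-vs-deficient severity comparisons, covariate-
#' adjusted sensitivity analyses). A single base seed fans out to per-stage
#' seeds as `seed + 1000 * stage`, so each stage is independently
#' reproducible.
#'
#' @param config a [SimulationConfig-class], the path to a YAML/JSON run
#'   configuration (see [readRunConfig()]), or a [RewardCohort-class].
#' @param outDir optional directory; when given, cohort tables, model JSON,
#'   DFH records, statistics and a markdown report are written there.
#' @param seed base seed for fold assignments (and simulation when `config`
#'   carries no seed of its own).
#' @param C soft-margin cost for the SVM.
#' @param folds cross-validation folds.
#' @return list with elements `cohort`, `hyperplane`, `normReference`,
#'   `cv`, `dfh`, `report` (the five result sections) and `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL, seed = 1L, C = 1,
                        folds = 10L) {
  analysis <- list()
  if (is.character(config) && length(config) == 1L) {
    rc <- readRunConfig(config)
    analysis <- rc$analysis
    if (!is.null(analysis$seed)) seed <- analysis$seed
    if (!is.null(analysis$cost)) C <- analysis$cost
    if (!is.null(analysis$folds)) folds <- analysis$folds
    config <- if (!is.null(rc$simulate)) rc$simulate else {
      feat <- readFeatureTable(rc$features)
      phen <- readPhenotypeTable(rc$phenotypes)
      rewardCohort(feat, phen)
    }
  }
  if (methods::is(config, "SimulationConfig")) {
    cohort <- simulateCohort(config)
  } else if (methods::is(config, "RewardCohort")) {
    cohort <- config
  } else stop("config must be a SimulationConfig, RewardCohort or path")

  ph <- phenotypes(cohort)
  if (!"group" %in% colnames(ph))
    stop("cohort phenotypes must carry a group column")
  trainIds <- ph$subject_id[ph$group == "TD_train"]
  if (length(trainIds) < 10L)
    warning("small training sample (n = ", length(trainIds),
            "): norming reference will be unstable")

  # stage 2: train final classifier; stage 3: grouped CV estimate
  hyperplane <- trainClassifier(cohort, trainIds, C = C, folds = folds,
                                seed = stageSeed(seed, 2L))
  cv <- groupedCvEvaluate(cohort, trainIds,
                          k = min(folds, length(trainIds)), C = C,
                          seed = stageSeed(seed, 3L))

  # stage 4: score and norm
  dfh <- scoreCohort(cohort, hyperplane)
  reference <- attr(dfh, "reference")

  # stage 5: downstream statistics
  signs <- if (is.null(hyperplane@selection))
    stats::setNames(as.integer(sign(hyperplane@weights)),
                    hyperplane@regionIds)
  else selectionSigns(hyperplane@selection)
  selectedFeatures <- data.frame(
    region_id = names(signs),
    sign = unname(signs),
    preference = ifelse(signs > 0, "reward", "punishment"))

  groupsAvail <- c("TD_train", "TD_test", "clinical")
  dxAvail <- intersect(.DIAGNOSES, colnames(ph))
  dxAvail <- dxAvail[vapply(dxAvail, function(d)
    any(ph$group == "clinical" & ph[[d]] %in% TRUE), logical(1))]
  catAll <- categoryTable(dfh, ph, groupsAvail)
  proportions <- sweep(catAll, 1L, rowSums(catAll), "/")

  tabTestClin <- categoryTable(dfh, ph, c("TD_test", "clinical"))
  tests <- list(
    patient_vs_TDtest_full5 = chiSquareTest(
      collapseBins(tabTestClin, "full5")),
    patient_vs_TDtest_low3 = suppressWarnings(chiSquareTest(
      collapseBins(tabTestClin, "low3"))),
    patient_vs_TDtest_high3 = suppressWarnings(chiSquareTest(
      collapseBins(tabTestClin, "high3"))),
    TDtrain_vs_TDtest_full5 = suppressWarnings(chiSquareTest(
      categoryTable(dfh, ph, c("TD_train", "TD_test")))))
  for (dx in dxAvail)
    tests[[paste0(dx, "_vs_TDtest_full5")]] <- suppressWarnings(
      chiSquareTest(categoryTable(dfh, ph, c("TD_test", dx))))

  correlations <- correlateDFH(dfh, ph)

  severity <- list()
  for (sc in intersect(scaleNames(), colnames(ph))) {
    res <- tryCatch(compareSymptomSeverity(dfh, ph, sc),
                    error = function(e) NULL)
    if (!is.null(res)) severity[[sc]] <- res
  }

  # sensitivity: covariate-adjusted typical-vs-deficient comparisons
  sensitivity <- list()
  covars <- intersect(c("age", "IQ", "sex"), colnames(ph))
  if (length(covars) && length(severity)) {
    testIds <- ph$subject_id[ph$group %in% c("TD_test", "clinical")]
    grp <- splitByDeficiency(dfh, testIds)
    ids <- c(grp$typical, grp$deficient)
    gvec <- factor(rep(c("typical", "deficient"),
                       c(length(grp$typical), length(grp$deficient))),
                   levels = c("typical", "deficient"))
    idx <- match(ids, ph$subject_id)
    for (sc in names(severity)) {
      res <- tryCatch(covariateAdjustedComparison(
        ph[[sc]][idx], gvec, ph[idx, covars, drop = FALSE]),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(res)) sensitivity[[sc]] <- res
    }
  }

  report <- list(
    cvMetrics = list(accuracy = cv@accuracy, sensitivity = cv@sensitivity,
                     specificity = cv@specificity,
                     confusion = as.list(cv@confusion), k = cv@k),
    selectedFeatures = selectedFeatures,
    categoryProportions = proportions,
    contingencyTests = tests,
    correlations = correlations,
    severityComparisons = severity,
    sensitivityAnalyses = sensitivity)

  manifest <- list(
    tool = "rewardDFH",
    version = as.character(utils::packageVersion("rewardDFH")),
    seed = seed,
    configHash = digestConfig(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    fileDigests = list())

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- writeCohort(cohort, outDir)
    paths <- c(paths, writeResultsBundle(
      list(hyperplane = hyperplane, normReference = reference, dfh = dfh,
           statistics = report[c("cvMetrics", "contingencyTests",
                                 "correlations", "severityComparisons",
                                 "sensitivityAnalyses")]), outDir))
    reportPath <- file.path(outDir, "report.md")
    writeLines(renderReport(report, reference), reportPath)
    paths <- c(paths, report = reportPath)
    manifest$fileDigests <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }

  list(cohort = cohort, hyperplane = hyperplane,
       normReference = reference, cv = cv, dfh = dfh, report = report,
       manifest = manifest)
}

digestConfig <- function(config) {
  ser <- if (methods::is(config, "SimulationConfig")) {
    slots <- methods::slotNames(config)
    stats::setNames(lapply(slots, methods::slot, object = config), slots)
  } else list(class = class(config))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(ser, tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

renderReport <- function(report, reference) {
  fm <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c(
    "# Reward-response classifier report", "",
    "## Cross-validated classifier performance", "",
    sprintf("- accuracy: %s", fm(report$cvMetrics$accuracy)),
    sprintf("- sensitivity: %s", fm(report$cvMetrics$sensitivity)),
    sprintf("- specificity: %s", fm(report$cvMetrics$specificity)),
    sprintf("- folds: %d", report$cvMetrics$k), "",
    "## Selected features", "",
    sprintf("%d regions (%d reward-preferring, %d punishment-preferring)",
            nrow(report$selectedFeatures),
            sum(report$selectedFeatures$sign > 0),
            sum(report$selectedFeatures$sign < 0)), "",
    paste0("- ", report$selectedFeatures$region_id, ": ",
           report$selectedFeatures$preference), "",
    "## Normed reward DFH category proportions", "",
    sprintf("norming reference: mu = %s, sigma = %s (n = %d)",
            fm(reference@mu), fm(reference@sigma), reference@n), "",
    paste(utils::capture.output(print(round(
      report$categoryProportions, 4))), collapse = "\n"), "",
    "## Contingency tests", "")
  for (nm in names(report$contingencyTests)) {
    t <- report$contingencyTests[[nm]]
    lines <- c(lines, sprintf(
      "- %s: chi-square = %s, df = %s, p = %s (N = %d)", nm,
      fm(t$statistic), as.character(t$df), fm(t$p), t$n))
  }
  lines <- c(lines, "", "## DFH correlations", "",
    paste(utils::capture.output(print(report$correlations,
                                      row.names = FALSE)),
          collapse = "\n"), "",
    "## Symptom severity: typical vs deficient reward response", "")
  for (nm in names(report$severityComparisons)) {
    s <- report$severityComparisons[[nm]]
    lines <- c(lines, sprintf(
      "- %s: typical %s (n=%d) vs deficient %s (n=%d); t = %s, p = %s",
      nm, fm(s$mean_typical), s$n_typical, fm(s$mean_deficient),
      s$n_deficient, fm(s$t), fm(s$p)))
  }
  lines
}
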