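#' @include AllClasses.R dfh.R utils.R
NULL

# resolve a group specifier into subject ids:
# "TD_train"/"TD_test"/"clinical" select by group label; "CD"/"ADHD"/
# "MDD"/"GAD" select clinical subjects carrying that diagnosis flag
resolveGroup <- function(spec, phenotypes) {
  if (spec %in% .GROUPS)
    return(phenotypes$subject_id[phenotypes$group == spec])
  if (spec %in% .DIAGNOSES) {
    if (!spec %in% colnames(phenotypes))
      stop("phenotypes lack diagnosis flag: ", spec)
    return(phenotypes$subject_id[phenotypes$group == "clinical" &
                                   phenotypes[[spec]] %in% TRUE])
  }
  stop("unknown group spec: ", spec)
}

#' Cross-tabulate groups by normed reward-DFH category
#'
#' Counts subjects of two or more disjoint (or diagnosis-overlapping)
#' groups in each of the five s.d. categories of the reward condition.
#' Diagnosis-based specs ("CD", "ADHD", "MDD", "GAD") select clinical
#' subjects carrying that flag, so a comorbid subject contributes to each
#' diagnosis-specific comparison it qualifies for.
#'
#' @param dfh DFH records from [scoreCohort()].
#' @param phenotypes per-subject phenotype data.frame.
#' @param groups character vector of group specs, or a named list of
#'   subject-id vectors.
#' @return integer matrix, one row per group, columns the five categories
#'   ordered `below_minus2` .. `above_plus2`.
#' @export
categoryTable <- function(dfh, phenotypes, groups = c("TD_test", "clinical")) {
  rew <- dfh[dfh$condition == "reward", ]
  if (!is.list(groups)) {
    groups <- stats::setNames(
      lapply(groups, resolveGroup, phenotypes = phenotypes), groups)
  }
  counts <- t(vapply(groups, function(ids) {
    if (!length(ids)) stop("empty group in group spec")
    table(factor(rew$category[rew$subject_id %in% ids],
                 levels = .CATEGORIES))
  }, integer(length(.CATEGORIES))))
  colnames(counts) <- .CATEGORIES
  counts
}

#' Collapse the five categories into a reporting scheme
#'
#' `full5` keeps all bins; `low3` keeps the normative and the two
#' low-response bins (columns ordered normative, -2..-1, < -2); `high3`
#' keeps the normative and the two high-response bins (normative, +1..+2,
#' > +2). Subjects in bins outside the scheme are dropped; the dropped
#' count is attached as `attr(, "dropped")`.
#'
#' @param table counts matrix from [categoryTable()] (columns in
#'   low-to-high category order).
#' @param scheme one of `"full5"`, `"low3"`, `"high3"`.
#' @return collapsed counts matrix.
#' @export
collapseBins <- function(table, scheme = c("full5", "low3", "high3")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(table), ncol(table) == 5L)
  keep <- switch(scheme,
    full5 = 1:5,
    low3 = c(3L, 2L, 1L),   # normative, -2..-1, < -2
    high3 = c(3L, 4L, 5L))  # normative, +1..+2, > +2
  out <- table[, keep, drop = FALSE]
  colnames(out) <- .CATEGORIES[keep]
  attr(out, "dropped") <- sum(table) - sum(out)
  attr(out, "scheme") <- scheme
  out
}

#' Pearson chi-square test of homogeneity on a contingency table
#'
#' Pearson chi-square without continuity correction, df = (r-1)(c-1).
#' Columns with zero total (expected count zero in every cell) are dropped
#' with a warning and the df adjusted; if fewer than two non-degenerate
#' columns remain the test is reported as degenerate (NA statistic) with a
#' warning.
#'
#' @param table counts matrix (>= 2 rows).
#' @return list with `statistic`, `df`, `p`, `n`, `test`, `scheme`,
#'   `droppedColumns`.
#' @examples
#' chiSquareTest(rbind(c(10, 20), c(20, 10)))   # statistic 20/3, df 1
#' @export
chiSquareTest <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 2L)
  if (any(table < 0)) stop("counts must be >= 0")
  scheme <- attr(table, "scheme")
  zero <- colSums(table) == 0
  dropped <- colnames(table)[zero]
  if (any(zero)) {
    warning("dropping zero-count column(s): ",
            paste(dropped, collapse = ", "))
    table <- table[, !zero, drop = FALSE]
  }
  base <- list(n = sum(table), test = "pearson_chi_square",
               scheme = if (is.null(scheme)) "custom" else scheme,
               droppedColumns = as.character(dropped))
  if (ncol(table) < 2L || any(rowSums(table) == 0)) {
    warning("degenerate table: test skipped")
    return(c(list(statistic = NA_real_, df = NA_integer_, p = NA_real_),
             base))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  c(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value)), base)
}

#' Correlate DFH with phenotype variables
#'
#' Pearson correlations of each variable against the reward-condition DFH
#' and, separately, the punishment-condition DFH (`d_pun = -d`, larger =
#' stronger punishment-side response), with pairwise-complete observations
#' and two-sided p values tiered at 0.05 / 0.01 / 0.005.
#'
#' @param dfh DFH records from [scoreCohort()].
#' @param phenotypes per-subject phenotype data.frame.
#' @param variables phenotype columns to correlate; default age, IQ and all
#'   clinical scales present.
#' @param subjects subject filter; default the test samples
#'   (`TD_test` and `clinical`).
#' @return data.frame with one row per variable x condition: `variable`,
#'   `condition`, `r`, `p`, `n`, `tier` (`NA` r when fewer than 3 complete
#'   pairs).
#' @export
correlateDFH <- function(dfh, phenotypes, variables = NULL,
                         subjects = NULL) {
  if (is.null(subjects))
    subjects <- phenotypes$subject_id[
      phenotypes$group %in% c("TD_test", "clinical")]
  if (is.null(variables))
    variables <- intersect(c("age", "IQ", scaleNames()),
                           colnames(phenotypes))
  missing <- setdiff(variables, colnames(phenotypes))
  if (length(missing))
    stop("variables absent from phenotypes: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (cond in .CONDITIONS) {
    rows <- dfh[dfh$condition == cond & dfh$subject_id %in% subjects, ]
    dVal <- if (cond == "punishment") rows$d_pun else rows$d
    idx <- match(rows$subject_id, phenotypes$subject_id)
    for (v in variables) {
      y <- phenotypes[[v]][idx]
      if (is.character(y) || is.factor(y)) next
      ok <- stats::complete.cases(dVal, y)
      if (sum(ok) < 3L) {
        out[[length(out) + 1L]] <- data.frame(
          variable = v, condition = cond, r = NA_real_, p = NA_real_,
          n = sum(ok), tier = NA_character_)
        next
      }
      ct <- stats::cor.test(dVal[ok], y[ok], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        variable = v, condition = cond, r = unname(ct$estimate),
        p = ct$p.value, n = sum(ok), tier = significanceTier(ct$p.value))
    }
  }
  do.call(rbind, out)
}

# split filtered subjects into typical / deficient reward-response groups
splitByDeficiency <- function(dfh, subjects,
                              deficientDef = c("below_minus2",
                                               "below_minus1")) {
  deficientDef <- match.arg(deficientDef)
  rew <- dfh[dfh$condition == "reward" & dfh$subject_id %in% subjects, ]
  typical <- rew$subject_id[rew$category == "normative"]
  deficient <- if (deficientDef == "below_minus2")
    rew$subject_id[rew$category == "below_minus2"]
  else rew$subject_id[rew$z < -1]
  list(typical = typical, deficient = deficient)
}

#' Compare symptom severity between typical and deficient responders
#'
#' Welch two-sample t test of a clinical scale between subjects with a
#' normative reward response (-1 to 1 training s.d.) and subjects with a
#' deficient one (below -2 s.d. by default, or below -1 s.d.). The t
#' statistic is typical minus deficient, so elevated symptoms in the
#' deficient group give negative t.
#'
#' @param dfh DFH records from [scoreCohort()].
#' @param phenotypes per-subject phenotype data.frame.
#' @param scale phenotype column to compare.
#' @param deficientDef `"below_minus2"` (default) or `"below_minus1"`.
#' @param subjects subject filter; default `TD_test` plus `clinical`.
#' @return list with group means/s.d./n, `t`, `df` (Welch), `p`.
#' @export
compareSymptomSeverity <- function(dfh, phenotypes, scale,
                                   deficientDef = "below_minus2",
                                   subjects = NULL) {
  if (!scale %in% colnames(phenotypes))
    stop("unknown scale: ", scale)
  if (is.null(subjects))
    subjects <- phenotypes$subject_id[
      phenotypes$group %in% c("TD_test", "clinical")]
  grp <- splitByDeficiency(dfh, subjects, deficientDef)
  val <- function(ids) {
    v <- phenotypes[[scale]][match(ids, phenotypes$subject_id)]
    v[!is.na(v)]
  }
  xT <- val(grp$typical); xD <- val(grp$deficient)
  if (length(xT) < 2L || length(xD) < 2L)
    stop("a group has fewer than 2 complete observations")
  tt <- stats::t.test(xT, xD)
  list(scale = scale, deficient_def = deficientDef,
       mean_typical = mean(xT), sd_typical = stats::sd(xT),
       n_typical = length(xT),
       mean_deficient = mean(xD), sd_deficient = stats::sd(xD),
       n_deficient = length(xD),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, test = "welch_t")
}

#' Covariate-adjusted group comparison
#'
#' Sensitivity analysis: ordinary least-squares fit of an outcome on a
#' two-level group indicator plus covariates (age, IQ, sex, ...), reported
#' alongside the unadjusted Welch comparison. Collinear covariates are
#' detected; the adjusted model is then skipped with a warning.
#'
#' @param outcome numeric outcome per subject.
#' @param group two-level factor/logical per subject.
#' @param covariates data.frame of covariates (numeric or factor columns).
#' @return list with `adjusted` (group coefficient, se, t, p, df or NA when
#'   skipped) and `unadjusted` (Welch comparison).
#' @export
covariateAdjustedComparison <- function(outcome, group, covariates) {
  stopifnot(length(outcome) == length(group),
            nrow(covariates) == length(outcome))
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("group must have exactly two levels")
  dat <- data.frame(.y = outcome, .g = group, covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (min(table(droplevels(dat$.g))) < 2L)
    stop("fewer than 2 complete cases in a group")
  tt <- stats::t.test(.y ~ .g, data = dat)
  # group effect on the lm coding scale: mean(level 2) - mean(level 1)
  unadj <- list(estimate = unname(diff(tt$estimate)),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  fit <- stats::lm(.y ~ ., data = dat[, c(".y", ".g",
                                          colnames(covariates))])
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear covariates; adjusted model skipped")
    adj <- list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, df = NA_integer_, skipped = TRUE)
  } else {
    cf <- summary(fit)$coefficients
    row <- grep("^\\.g", rownames(cf))
    adj <- list(estimate = cf[row, 1L], se = cf[row, 2L], t = cf[row, 3L],
                p = cf[row, 4L], df = fit$df.residual, skipped = FALSE)
  }
  list(adjusted = adj, unadjusted = unadj,
       n = nrow(dat), covariates = colnames(covariates))
}
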