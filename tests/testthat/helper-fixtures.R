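# small study-shaped configurations used across tests; region count and
# group sizes are reduced so single tests run in seconds

smallConfig <- function(seed = 1L, ...) {
  args <- list(nTdTrain = 20L, nTdTest = 12L, nClinical = 30L,
               nRegions = 40L, rewardRegions = 1:8,
               punishmentRegions = 9:14, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulationConfig, args)
}

# a hand-built scored-record table for the statistics layer
dfhRecords <- function(subject_id, z, group = NULL,
                       condition = "reward") {
  data.frame(subject_id = subject_id, condition = condition,
             group = if (is.null(group)) NA_character_ else group,
             d = z, d_pun = NA_real_, z = z,
             category = categorizeZ(z), stringsAsFactors = FALSE)
}

# standardized training matrix + labels for selection/classifier tests
trainingMatrix <- function(cohort) {
  ids <- phenotypes(cohort)$subject_id[
    phenotypes(cohort)$group == "TD_train"]
  std <- fitStandardizer(cohort, ids)
  cd <- SummarizedExperiment::colData(cohort)
  keep <- cd$subject_id %in% ids
  list(x = applyStandardizer(std, cohort, subjects = ids),
       condition = as.character(cd$condition[keep]),
       subject = cd$subject_id[keep], std = std, ids = ids)
}
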