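# internal helpers shared across modules

# run code under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# per-stage seeds fanned out from a single base seed; documented scheme so
# every pipeline stage is independently reproducible
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1000 * stage) %% .Machine$integer.max)
}

# clinical instrument definitions: plausible score ranges plus the default
# generative coupling (intercept, slope on 1 - gain, residual s.d.).
# Couplings are nonzero for the scales tied to reward-response integrity
# (conduct, hyperactivity/ADHD, depression/emotional, callousness, neglect);
# anxiety, proactive aggression, abuse, substance-use and irritability
# scales are uncoupled.
scaleDefinitions <- function() {
  def <- rbind(
    SDQ_CP            = c(0, 10, 2.0,  8.0, 1.5),
    RPAQ_Reactive     = c(0, 22, 5.0, 10.0, 3.0),
    RPAQ_Proactive    = c(0, 24, 2.0,  0.0, 2.5),
    Conners_ADHD      = c(0, 30, 8.0, 18.0, 5.0),
    SDQ_Hyperactivity = c(0, 10, 3.0,  8.0, 1.5),
    SDQ_Emotional     = c(0, 10, 2.5,  7.0, 1.5),
    CDI               = c(0, 54, 8.0, 25.0, 6.0),
    SCARED_Total      = c(0, 82, 15.0, 0.0, 8.0),
    SCARED_GAD        = c(0, 18, 4.0,  0.0, 2.5),
    CTQ_Abuse         = c(15, 75, 18.0, 0.0, 4.0),
    CTQ_Neglect       = c(10, 50, 13.0, 12.0, 4.0),
    AUDIT             = c(0, 40, 1.0,  0.0, 2.0),
    CUDIT             = c(0, 32, 1.0,  0.0, 2.0),
    ICU               = c(0, 72, 20.0, 20.0, 6.0),
    ARI               = c(0, 12, 2.0,  0.0, 1.5))
  colnames(def) <- c("lo", "hi", "intercept", "beta", "noiseSd")
  as.data.frame(def)
}

scaleNames <- function() rownames(scaleDefinitions())

# region labels: cortical parcels plus (when room allows) 12 bilateral
# subcortical structures appended last, mirroring a 400+12 atlas layout
regionLabels <- function(nRegions) {
  sub <- as.vector(outer(c("Thalamus", "Caudate", "Putamen", "Accumbens",
                           "Hippocampus", "Amygdala"),
                         c("L", "R"), paste, sep = "_"))
  if (nRegions > 12L) {
    nCort <- nRegions - 12L
    c(sprintf("Parcel_%03d", seq_len(nCort)), sub)
  } else {
    sprintf("Parcel_%03d", seq_len(nRegions))
  }
}

# write a data.frame as TSV with full double precision so read-back is exact
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# significance tier used in correlation reporting
significanceTier <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.005, "0.005",
      ifelse(p < 0.01, "0.01",
        ifelse(p < 0.05, "0.05", "ns"))))
}

l2norm <- function(x) sqrt(sum(x^2))
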