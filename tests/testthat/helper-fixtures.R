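# small in-code fixtures shared across test files

toyRunInfo <- function(n, roles = rep("study", n), groups = rep("control", n),
                       batches = rep(0L, n)) {
  data.frame(run_id = sprintf("R%02d", seq_len(n)),
             sample_id = sprintf("S%02d", seq_len(n)),
             replicate_index = 1L, batch = batches,
             injection_order = stats::ave(seq_len(n), batches,
                                          FUN = seq_along),
             role = roles, group = groups, stringsAsFactors = FALSE)
}

toyFeatureInfo <- function(p, mode = "RP") {
  data.frame(feature_id = sprintf("F%03d", seq_len(p)),
             mz = seq(100, 900, length.out = p),
             rt = seq(0.5, if (mode == "RP") 11 else 8, length.out = p),
             mode = rep(mode, p), stringsAsFactors = FALSE)
}

# a config small enough for unit tests, planted sets scaled down with it
smallConfig <- function(n_features, ...) {
  syntheticConfig(n_features = n_features, n_fentanyl_features = 20L,
                  n_opioid_features = 10L, n_drug_features_per_class = 5L,
                  ...)
}

# random positive table; deterministic given seed
randomTable <- function(n, p, seed = 1, zeros = 0, mode = "RP") {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p, 8, 1)), n, p)
  if (zeros > 0) m[sample(length(m), floor(zeros * length(m)))] <- 0
  PeakTable(m, toyRunInfo(n), toyFeatureInfo(p, mode))
}

# replicate-structured table: n_samples x n_reps study runs
replicateTable <- function(n_samples, n_reps, p, seed = 1, noise_sd = 0.05) {
  set.seed(seed)
  base <- matrix(exp(rnorm(n_samples * p, 8, 1)), n_samples, p)
  m <- base[rep(seq_len(n_samples), each = n_reps), ] *
    exp(matrix(rnorm(n_samples * n_reps * p, 0, noise_sd),
               n_samples * n_reps, p))
  ri <- data.frame(run_id = sprintf("S%02d_r%d",
                                    rep(seq_len(n_samples), each = n_reps),
                                    rep(seq_len(n_reps), n_samples)),
                   sample_id = sprintf("S%02d",
                                       rep(seq_len(n_samples), each = n_reps)),
                   replicate_index = rep(seq_len(n_reps), n_samples),
                   batch = 0L,
                   injection_order = seq_len(n_samples * n_reps),
                   role = "study", group = "control",
                   stringsAsFactors = FALSE)
  PeakTable(m, ri, toyFeatureInfo(p))
}

# exclusion lists built from a table's own ground-truth drug features
truthExclusions <- function(table, truth) {
  ids <- unlist(truth$drug_feature_ids)
  fi <- featureInfo(table)
  k <- match(ids, fi$feature_id)
  exclusionList(fi$mz[k], fi$rt[k], label = ids)
}

makeClassTables <- function(n_class, n_other, p, seed, displace = NULL) {
  # exchangeable gaussian data; optional named displacement (feature -> SDs)
  set.seed(seed)
  latent <- matrix(rnorm((n_class + n_other) * 3), n_class + n_other, 3)
  W <- matrix(rnorm(3 * p, 0, 0.6), 3, p)
  m <- 100 + latent %*% W + matrix(rnorm((n_class + n_other) * p),
                                   n_class + n_other, p)
  if (!is.null(displace))
    for (j in names(displace))
      m[seq_len(n_other) + n_class, as.integer(j)] <-
        m[seq_len(n_other) + n_class, as.integer(j)] + displace[[j]]
  fi <- toyFeatureInfo(p)
  cls <- PeakTable(m[seq_len(n_class), , drop = FALSE],
                   toyRunInfo(n_class, groups = rep("target", n_class)), fi)
  oth <- PeakTable(m[seq_len(n_other) + n_class, , drop = FALSE],
                   toyRunInfo(n_other, groups = rep("rest", n_other)), fi)
  list(cls = cls, oth = oth)
}
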