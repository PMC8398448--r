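#' @include core_tables.R
NULL

#' Parameterization of a simulated LC-HRMS study
#'
#' A `SyntheticConfig` fixes every aspect of a simulated cohort: design
#' sizes, log-normal baseline and noise magnitudes, batch effects and QC
#' interleaving, detection-limit sparsity, and the planted fentanyl-
#' specific and opioid-shared latent shifts that downstream models are
#' asked to recover. Identical configs (including the seed) reproduce
#' bitwise-identical tables.
#'
#' @param n_features features per chromatographic mode (default 2000,
#'   the scale of a sparsity-filtered untargeted urine table).
#' @param group_sizes named integer vector of samples per group; the
#'   default is the 18 control / 24 fentanyl / 12 opioids / 27 other-drugs
#'   cohort (81 samples).
#' @param n_replicates technical replicates per sample (default 3).
#' @param n_batches analytical batches (default 3).
#' @param qc_every a QC injection opens each batch and recurs every this
#'   many study injections (default 10).
#' @param baseline_log_mean,baseline_log_sd natural-log mean and SD of
#'   per-feature baseline abundance.
#' @param bio_log_sd log-scale SD of per-sample biological variation.
#' @param replicate_cv log-scale SD of technical-replicate noise
#'   (approximately the CV for small values).
#' @param batch_sd log-scale SD of the per-batch multiplicative factor.
#' @param sparsity_rate fraction of study intensities zeroed at the
#'   detection limit, in `[0, 1)`.
#' @param n_fentanyl_features,n_opioid_features sizes of the
#'   fentanyl-specific and opioid-shared fingerprint feature sets.
#' @param n_drug_features_per_class parent-drug/direct-metabolite
#'   features expressed only in each non-control group (these are what
#'   exclusion lists remove).
#' @param n_effect_blocks correlated blocks the fingerprint features are
#'   split into; the planted shift is low-rank, not per-feature
#'   independent.
#' @param effect_sd SD of the per-sample, per-block latent activation
#'   around 1; sets the within-class heterogeneity of the fingerprint.
#' @param fentanyl_effect,opioid_effect log2 fold-change magnitudes of
#'   the planted shifts.
#' @param is_area_mean,is_area_cv mean and CV of the internal-standard
#'   area in QC injections.
#' @param treatments,times,n_repetitions in vitro design: treatment
#'   labels (dose in the label), collection times in hours, and
#'   repetitions per condition. Defaults give 12 x 4 x 2 = 96 runs.
#' @param seed integer random seed; all randomness flows from it through
#'   named substreams.
#' @return a `SyntheticConfig` object.
#' @export
syntheticConfig <- function(n_features = 2000L,
                            group_sizes = c(control = 18L, fentanyl = 24L,
                                            opioids = 12L, other_drugs = 27L),
                            n_replicates = 3L, n_batches = 3L, qc_every = 10L,
                            baseline_log_mean = 11, baseline_log_sd = 1.5,
                            bio_log_sd = 0.4, replicate_cv = 0.1,
                            batch_sd = 0.3, sparsity_rate = 0.3,
                            n_fentanyl_features = 60L,
                            n_opioid_features = 40L,
                            n_drug_features_per_class = 15L,
                            n_effect_blocks = 4L, effect_sd = 0.2,
                            fentanyl_effect = 2, opioid_effect = 1,
                            is_area_mean = 1e6, is_area_cv = 0.05,
                            treatments = c("control",
                                           "fentanyl_0.5uM", "fentanyl_5uM",
                                           "fentanyl_50uM", "diazepam_5uM",
                                           "U47700_5uM", "MDMA_5uM",
                                           "heroin_5uM", "ketoprofen_5uM",
                                           "cocaine_5uM",
                                           "fentanyl_heroin_5uM",
                                           "control_solvent"),
                            times = c(6, 12, 24, 48),
                            n_repetitions = 2L, seed = 1L) {
  cfg <- list(n_features = as.integer(n_features),
              group_sizes = group_sizes,
              n_replicates = as.integer(n_replicates),
              n_batches = as.integer(n_batches),
              qc_every = as.integer(qc_every),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              bio_log_sd = bio_log_sd, replicate_cv = replicate_cv,
              batch_sd = batch_sd, sparsity_rate = sparsity_rate,
              n_fentanyl_features = as.integer(n_fentanyl_features),
              n_opioid_features = as.integer(n_opioid_features),
              n_drug_features_per_class = as.integer(n_drug_features_per_class),
              n_effect_blocks = as.integer(n_effect_blocks),
              effect_sd = effect_sd,
              fentanyl_effect = fentanyl_effect,
              opioid_effect = opioid_effect,
              is_area_mean = is_area_mean, is_area_cv = is_area_cv,
              treatments = treatments, times = times,
              n_repetitions = as.integer(n_repetitions),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_features > 0, length(group_sizes) > 0, all(group_sizes >= 0),
              n_replicates >= 1, n_batches >= 1, qc_every >= 1,
              replicate_cv >= 0, batch_sd >= 0, bio_log_sd >= 0,
              sparsity_rate >= 0, sparsity_rate < 1, is_area_cv >= 0,
              effect_sd >= 0, fentanyl_effect >= 0, opioid_effect >= 0)
    n_planted <- n_fentanyl_features + n_opioid_features +
      3L * n_drug_features_per_class
    stopifnot(n_planted <= n_features)
  })
  structure(cfg, class = "SyntheticConfig")
}

#' @rdname syntheticConfig
#' @param config an existing `SyntheticConfig`.
#' @export
reseed <- function(config, seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  config$seed <- as.integer(seed)
  config
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf("SyntheticConfig: %d features, %d samples x %d replicates, %d batches, seed %d\n",
              x$n_features, sum(x$group_sizes), x$n_replicates,
              x$n_batches, x$seed))
  invisible(x)
}

# named substreams: every stage of every output table seeds its own
# generator, so changing one stage's parameters never perturbs another
subSeed <- function(seed, stream, stage) {
  (as.numeric(seed) * 48271 + stream * 65537 + stage * 101) %% 2147483399 + 1
}
drawWith <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# shared run layout for the urine cohort: randomized sample order,
# contiguous batches, replicates injected consecutively, a QC opening
# each batch and recurring every qc_every study injections
urineLayout <- function(config) {
  gs <- config$group_sizes
  n_samples <- sum(gs)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  group <- rep(names(gs), gs)
  ord <- drawWith(subSeed(config$seed, 0, 1), sample.int(n_samples))
  sample_id <- sample_id[ord]; group <- group[ord]
  batch_of <- sort(rep_len(seq_len(config$n_batches) - 1L, n_samples))
  rows <- list(); qn <- 0L
  for (b in unique(batch_of)) {
    io <- 0L; since_qc <- 0L
    sid_b <- sample_id[batch_of == b]; grp_b <- group[batch_of == b]
    addqc <- function() {
      qn <<- qn + 1L; io <<- io + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        run_id = sprintf("QC%03d", qn), sample_id = sprintf("QC%03d", qn),
        replicate_index = 1L, batch = b, injection_order = io,
        role = "qc", group = NA_character_, stringsAsFactors = FALSE)
    }
    addqc()
    for (i in seq_along(sid_b)) {
      for (r in seq_len(config$n_replicates)) {
        io <- io + 1L; since_qc <- since_qc + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = sprintf("%s_r%d", sid_b[i], r), sample_id = sid_b[i],
          replicate_index = r, batch = b, injection_order = io,
          role = "study", group = grp_b[i], stringsAsFactors = FALSE)
        if (since_qc >= config$qc_every) { addqc(); since_qc <- 0L }
      }
    }
  }
  do.call(rbind, rows)
}

# one chromatographic mode of the urine study
urineMode <- function(config, layout, mode, stream) {
  p <- config$n_features
  rt_max <- unname(CHROM_MODES[mode])
  feat <- drawWith(subSeed(config$seed, stream, 1), data.frame(
    feature_id = sprintf("%s%05d", mode, seq_len(p)),
    mz = runif(p, 50, 1000), rt = runif(p, 0.1, rt_max - 0.1),
    mode = mode, stringsAsFactors = FALSE))
  baseline <- drawWith(subSeed(config$seed, stream, 2),
                       exp(rnorm(p, config$baseline_log_mean,
                                 config$baseline_log_sd)))

  # disjoint planted feature sets
  idx <- seq_len(p)
  fent_idx <- idx[seq_len(config$n_fentanyl_features)]
  op_idx <- idx[config$n_fentanyl_features + seq_len(config$n_opioid_features)]
  classes <- setdiff(names(config$group_sizes), "control")
  drug_idx <- list()
  off <- config$n_fentanyl_features + config$n_opioid_features
  for (cl in classes) {
    drug_idx[[cl]] <- idx[off + seq_len(config$n_drug_features_per_class)]
    off <- off + config$n_drug_features_per_class
  }
  # scramble positions so planted features are not the leading columns
  perm <- drawWith(subSeed(config$seed, stream, 3), sample.int(p))
  fent_idx <- perm[fent_idx]; op_idx <- perm[op_idx]
  drug_idx <- lapply(drug_idx, function(i) perm[i])
  # fingerprint features live in the well-detected abundance range: a
  # shift of a feature sitting at the detection limit would be censored
  # away and could never have been discovered as a marker
  fp_idx <- c(fent_idx, op_idx)
  baseline[fp_idx] <- drawWith(subSeed(config$seed, stream, 10),
                               exp(rnorm(length(fp_idx),
                                         config$baseline_log_mean + 1.5,
                                         config$baseline_log_sd / 3)))

  samples <- unique(layout$sample_id[layout$role == "study"])
  groups <- layout$group[match(samples, layout$sample_id)]
  ns <- length(samples)

  eff <- drawWith(subSeed(config$seed, stream, 4), {
    sgn_f <- sample(c(-1, 1), length(fent_idx), replace = TRUE)
    sgn_o <- sample(c(-1, 1), length(op_idx), replace = TRUE)
    blk_f <- rep_len(seq_len(config$n_effect_blocks), length(fent_idx))
    blk_o <- rep_len(seq_len(config$n_effect_blocks), length(op_idx))
    act_f <- matrix(rnorm(ns * config$n_effect_blocks, 1, config$effect_sd),
                    ns, config$n_effect_blocks)
    act_o <- matrix(rnorm(ns * config$n_effect_blocks, 1, config$effect_sd),
                    ns, config$n_effect_blocks)
    list(sgn_f = sgn_f, sgn_o = sgn_o, blk_f = blk_f, blk_o = blk_o,
         act_f = act_f, act_o = act_o)
  })
  # per-sample log2 shift matrix (samples x features), low-rank by blocks
  shift <- matrix(0, ns, p)
  in_f <- groups == "fentanyl"
  in_o <- groups %in% c("fentanyl", "opioids")
  for (b in seq_len(config$n_effect_blocks)) {
    jf <- fent_idx[eff$blk_f == b]
    shift[in_f, jf] <- shift[in_f, jf] +
      outer(eff$act_f[in_f, b], eff$sgn_f[eff$blk_f == b] * config$fentanyl_effect)
    jo <- op_idx[eff$blk_o == b]
    shift[in_o, jo] <- shift[in_o, jo] +
      outer(eff$act_o[in_o, b], eff$sgn_o[eff$blk_o == b] * config$opioid_effect)
  }

  bio <- drawWith(subSeed(config$seed, stream, 5),
                  matrix(exp(rnorm(ns * p, 0, config$bio_log_sd)), ns, p))
  drug_level <- drawWith(subSeed(config$seed, stream, 6),
                         matrix(exp(rnorm(ns * p, config$baseline_log_mean + 1,
                                          config$baseline_log_sd / 2)), ns, p))
  # sample-level expected profile
  prof <- sweep(bio, 2, baseline, "*") * 2^shift
  for (cl in classes) {
    j <- drug_idx[[cl]]
    prof[, j] <- 0                         # absent outside the owning group
    ing <- groups == cl
    prof[ing, j] <- matrix(drug_level[ing, j], sum(ing), length(j))
  }

  batch_factor <- drawWith(subSeed(config$seed, stream, 7),
                           exp(rnorm(config$n_batches, 0, config$batch_sd)))
  names(batch_factor) <- as.character(sort(unique(layout$batch)))

  n_runs <- nrow(layout)
  repn <- drawWith(subSeed(config$seed, stream, 8),
                   matrix(exp(rnorm(n_runs * p, 0, config$replicate_cv)),
                          n_runs, p))
  m <- matrix(0, n_runs, p)
  is_study <- layout$role == "study"
  srow <- match(layout$sample_id, samples)
  bf <- batch_factor[as.character(layout$batch)]
  m[is_study, ] <- prof[srow[is_study], , drop = FALSE] *
    repn[is_study, , drop = FALSE] * bf[is_study]

  # QC runs: RP = internal-standard injections; HILIC = urine pool
  is_qc <- layout$role == "qc"
  qc_draw <- drawWith(subSeed(config$seed, stream, 9), {
    list(is_area = rnorm(sum(is_qc), config$is_area_mean,
                         config$is_area_mean * config$is_area_cv),
         pool = matrix(exp(rnorm(sum(is_qc) * p, 0, config$replicate_cv)),
                       sum(is_qc), p))
  })
  if (mode == "RP") {
    is_feat <- data.frame(feature_id = "RP_IS_fentanylD5", mz = 342.25,
                          rt = 6.2, mode = "RP", stringsAsFactors = FALSE)
    feat <- rbind(feat, is_feat)
    m <- cbind(m, 0)
    m[is_qc, p + 1L] <- qc_draw$is_area * bf[is_qc]
  } else {
    pool_prof <- colMeans(prof)
    m[is_qc, ] <- qc_draw$pool * rep(pool_prof, each = sum(is_qc)) * bf[is_qc]
    layout$role[is_qc] <- "pool"
  }

  # detection-limit sparsity on the urine profiles (study + pool runs)
  if (config$sparsity_rate > 0) {
    urine_rows <- layout$role %in% c("study", "pool")
    vals <- m[urine_rows, seq_len(p), drop = FALSE]
    L <- quantile(vals, config$sparsity_rate, names = FALSE)
    vals[vals < L] <- 0
    m[urine_rows, seq_len(p)] <- vals
  }

  tab <- PeakTable(m, layout, feat,
                   provenance = sprintf("synthetic_urine(%s,seed=%d)",
                                        mode, config$seed))
  id <- feat$feature_id
  list(table = tab,
       truth = list(fentanyl_feature_ids = id[fent_idx],
                    opioid_feature_ids = id[op_idx],
                    drug_feature_ids = lapply(drug_idx, function(i) id[i]),
                    effect_sign_fentanyl = setNames(eff$sgn_f, id[fent_idx]),
                    batch_factors = batch_factor))
}

#' Generate a synthetic two-mode urine study
#'
#' Emits reverse-phase and HILIC peak tables over the same samples with
#' independent feature spaces and noise, plus the ground truth needed to
#' verify recovery. The generative model: per-feature log-normal
#' baselines; per-sample log-normal biological variation; a low-rank
#' fentanyl-specific shift (correlated feature blocks, fixed sign per
#' feature, 2^(+/- `fentanyl_effect`)) in the fentanyl group; an
#' opioid-shared shift in both the fentanyl and opioids groups; per-class
#' parent-drug features present only in their group; per-batch
#' multiplicative factors; technical-replicate noise; and detection-limit
#' zeroing of the lowest `sparsity_rate` fraction of urine intensities.
#' RP batches carry internal-standard QC injections, HILIC batches pool
#' injections.
#'
#' @param config a [syntheticConfig()].
#' @param modes which tables to generate (default both).
#' @return list with `rp`, `hilic` ([PeakTable-class] or NULL) and
#'   `truth` (per-mode ground-truth lists plus per-sample groups).
#' @export
generateUrineStudy <- function(config, modes = c("RP", "HILIC")) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!length(config$group_sizes) || sum(config$group_sizes) == 0)
    stop("group_sizes must name at least one non-empty group")
  layout <- urineLayout(config)
  rp <- if ("RP" %in% modes) urineMode(config, layout, "RP", 1L) else NULL
  hl <- if ("HILIC" %in% modes) urineMode(config, layout, "HILIC", 2L) else NULL
  st <- layout$role == "study"
  groups <- setNames(layout$group[st], layout$sample_id[st])
  groups <- groups[!duplicated(names(groups))]
  list(rp = rp$table, hilic = hl$table,
       truth = list(rp = rp$truth, hilic = hl$truth, groups = groups))
}

#' Generate a synthetic in vitro (cell-incubation) study
#'
#' Emits a full-factorial treatments x collection-times x repetitions
#' design over one reverse-phase feature space: a cell-line background
#' common to every run (so control-mean subtraction is meaningful) plus,
#' for each non-control treatment, planted metabolite features whose
#' expected intensity grows linearly with collection time (monotone
#' metabolization), all under log-normal replicate noise.
#'
#' @param config a [syntheticConfig()]; `treatments`, `times` and
#'   `n_repetitions` define the design.
#' @return list with `table` ([PeakTable-class]) and `truth` (planted
#'   feature ids per treatment).
#' @export
generateInvitroStudy <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  tr <- config$treatments
  if (!length(tr)) stop("no treatments supplied")
  p <- config$n_features
  feat <- drawWith(subSeed(config$seed, 3L, 1), data.frame(
    feature_id = sprintf("IV%05d", seq_len(p)),
    mz = runif(p, 50, 1000), rt = runif(p, 0.1, 11.9), mode = "RP",
    stringsAsFactors = FALSE))
  baseline <- drawWith(subSeed(config$seed, 3L, 2),
                       exp(rnorm(p, config$baseline_log_mean,
                                 config$baseline_log_sd)))
  active <- setdiff(tr, grep("^control", tr, value = TRUE))
  k <- config$n_drug_features_per_class
  stopifnot(length(active) * k <= p)
  planted <- split(seq_len(length(active) * k),
                   rep(seq_along(active), each = k))
  names(planted) <- active
  amp <- drawWith(subSeed(config$seed, 3L, 3),
                  exp(rnorm(length(active) * k,
                            config$baseline_log_mean, 0.5)))

  design <- expand.grid(rep = seq_len(config$n_repetitions),
                        time = config$times, treatment = tr,
                        stringsAsFactors = FALSE)
  n_runs <- nrow(design)
  noise <- drawWith(subSeed(config$seed, 3L, 4),
                    matrix(exp(rnorm(n_runs * p, 0, config$replicate_cv)),
                           n_runs, p))
  m <- matrix(baseline, n_runs, p, byrow = TRUE)
  for (a in seq_along(active)) {
    j <- planted[[active[a]]]
    base_a <- amp[(a - 1L) * k + seq_len(k)]
    grow <- design$treatment == active[a]
    m[, j] <- 0
    m[grow, j] <- outer(design$time[grow] / max(config$times), base_a)
  }
  m <- m * noise
  sample_id <- sprintf("%s_t%g", design$treatment, design$time)
  run_meta <- data.frame(
    run_id = sprintf("%s_r%d", sample_id, design$rep),
    sample_id = sample_id, replicate_index = design$rep, batch = 0L,
    injection_order = seq_len(n_runs), role = "study",
    group = design$treatment, stringsAsFactors = FALSE)
  tab <- PeakTable(m, run_meta, feat,
                   provenance = sprintf("synthetic_invitro(seed=%d)",
                                        config$seed))
  list(table = tab,
       truth = list(planted = lapply(planted,
                                     function(j) feat$feature_id[j]),
                    design = design))
}

#' Write ground-truth sidecar CSVs
#'
#' @param truth the `truth` element of [generateUrineStudy()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mode in intersect(c("rp", "hilic"), names(truth))) {
    tm <- truth[[mode]]
    if (is.null(tm)) next
    df <- rbind(
      data.frame(feature_id = tm$fentanyl_feature_ids, class = "fentanyl"),
      data.frame(feature_id = tm$opioid_feature_ids, class = "opioid_shared"),
      do.call(rbind, lapply(names(tm$drug_feature_ids), function(cl)
        data.frame(feature_id = tm$drug_feature_ids[[cl]],
                   class = paste0("drug_", cl)))))
    write.csv(df, file.path(dir, paste0("truth_features_", mode, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(truth$groups))
    write.csv(data.frame(sample_id = names(truth$groups),
                         group = unname(truth$groups)),
              file.path(dir, "truth_groups.csv"), row.names = FALSE)
  invisible(dir)
}
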