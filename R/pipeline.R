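#' @include simca.R
NULL

urineDefaults <- function() {
  list(mode = "urine",
       sparsity_min_fraction = 0.15,
       normalization = list(RP = "internal_standard", HILIC = "pool_profile"),
       is_feature = "RP_IS_fentanylD5",
       scaling = list(RP = "pareto", HILIC = "autoscale"),
       dp_threshold = list(RP = 1.5, HILIC = 4.5),
       K_candidates = 1:6, dpK = 4,
       distance_limit = sqrt(2), confidence = 0.95,
       target_class = "fentanyl", control_group = "control",
       subtract_control = FALSE, subtract_before_scaling = TRUE,
       replicate_confidence = 0.95, seed = 1L, output_dir = NULL)
}

invitroDefaults <- function() {
  list(mode = "invitro", scaling = "pareto", K = 3L,
       confidence = 0.95, control_group = "control", seed = 1L,
       output_dir = NULL)
}

#' Validate (and default-fill) a pipeline configuration
#'
#' Reads a YAML pipeline configuration, fills unset fields with the
#' defaults encoding the published analysis choices (RP: internal-
#' standard normalization, Pareto scaling, dp threshold 1.5; HILIC:
#' pool-profile normalization, autoscaling, dp threshold 4.5; acceptance
#' limit sqrt(2)), and checks types, ranges and that referenced paths
#' exist.
#'
#' @param path YAML file, or a named list already in memory.
#' @return a validated `PipelineConfig` (named list).
#' @export
validateConfig <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else as.list(path)
  mode <- user$mode %||% "urine"
  if (!mode %in% c("urine", "invitro")) stop("mode must be urine or invitro")
  cfg <- if (mode == "urine") urineDefaults() else invitroDefaults()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
      utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
  }
  if (mode == "urine") {
    stopifnot(cfg$sparsity_min_fraction > 0, cfg$sparsity_min_fraction <= 1,
              all(unlist(cfg$dp_threshold) >= 0), cfg$distance_limit > 0,
              cfg$confidence > 0, cfg$confidence < 1)
  }
  for (k in grep("_path$", names(cfg), value = TRUE))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configured path does not exist: ", cfg[[k]])
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stageLog <- function(log, stage, table) {
  msg <- sprintf("%s: %d runs x %d features", stage, nRuns(table),
                 nFeatures(table))
  message("[pipeline] ", msg)
  c(log, setNames(msg, stage))
}

# preprocessing shared by both urine modes; returns the averaged,
# cleaned table plus the stage log
urinePreprocessMode <- function(table, cfg, mode_name, exclusions) {
  log <- character()
  log <- stageLog(log, "input", table)
  table <- filterSparse(table, cfg$sparsity_min_fraction,
                        keep = cfg$is_feature)
  log <- stageLog(log, "filter_sparse", table)
  norm <- cfg$normalization[[mode_name]]
  table <- switch(norm,
    internal_standard = normalizeInternalStandard(table, cfg$is_feature),
    pool_profile = normalizePoolProfile(table),
    total_area = normalizeTotalArea(table),
    stop("unknown normalization: ", norm))
  log <- stageLog(log, paste0("normalize_", norm), table)
  scr <- screenReplicates(table, cfg$replicate_confidence)
  table <- scr$table
  log <- stageLog(log, "replicate_average", table)
  drop <- character()
  if (!is.null(exclusions))
    drop <- matchExclusions(table, exclusions)
  if (cfg$is_feature %in% rownames(table))
    drop <- union(drop, cfg$is_feature)     # the spiked standard is not urine
  if (length(drop)) {
    table <- dropFeatures(table, drop)
    log <- stageLog(log, "drop_excluded", table)
  }
  list(table = table, log = log, screening = scr)
}

#' Run the end-to-end urine classification pipeline
#'
#' Reproduces the full analysis for one cohort measured in both
#' chromatographic modes: sparsity filtering, batch normalization
#' (internal standard for RP, pool profile for HILIC), PCA-based
#' replicate screening and averaging, exclusion-list removal, one-class
#' SIMCA on the target class per mode (discriminant-power selection,
#' RMSECV model-order choice, sqrt(2) acceptance limit), cross-validated
#' confusion summaries, and serial RP-then-HILIC fusion. Group labels
#' are never consulted before the SIMCA stage.
#'
#' @param config a [validateConfig()] list (or anything it accepts).
#' @param tables optional named list `list(rp =, hilic =)` of
#'   [PeakTable-class]s; otherwise `config$rp_table_path` etc. are read.
#' @param exclusions optional named list `list(rp =, hilic =)` of
#'   [exclusionList()]s.
#' @return list with per-mode results (`rp`, `hilic`: preprocessed
#'   table, model, cross-validated decisions, confusion), `fused`
#'   decisions, a [ConfusionSummary-class] for the fused rule, and the
#'   stage `log`. Written to `config$output_dir` as CSV/PNG when set.
#' @export
runUrinePipeline <- function(config, tables = NULL, exclusions = NULL) {
  cfg <- validateConfig(config)
  if (is.null(tables)) {
    tables <- list(
      rp = readPeakTable(cfg$rp_table_path, cfg$rp_metadata_path, mode = "RP"),
      hilic = readPeakTable(cfg$hilic_table_path, cfg$hilic_metadata_path,
                            mode = "HILIC"))
  }
  res <- list(log = list())
  for (mode_name in c("RP", "HILIC")) {
    key <- tolower(mode_name)
    pre <- urinePreprocessMode(tables[[key]], cfg, mode_name,
                               exclusions[[key]])
    tab <- pre$table
    ri <- runInfo(tab)
    cls <- tab[, ri$group %in% cfg$target_class]
    oth <- tab[, !(ri$group %in% cfg$target_class)]
    cv <- crossValidatedDecisions(
      cls, oth, K_candidates = cfg$K_candidates,
      dp_threshold = cfg$dp_threshold[[mode_name]],
      method = cfg$scaling[[mode_name]],
      distance_limit = cfg$distance_limit, confidence = cfg$confidence,
      dpK = cfg$dpK)
    res$log[[key]] <- c(pre$log,
                        setNames(sprintf("simca: K=%d, %d selected features",
                                         cv$model@K,
                                         length(cv$model@selected_features)),
                                 "simca"))
    res[[key]] <- list(table = tab, screening = pre$screening,
                       model = cv$model, confusion = cv$confusion,
                       class_decisions = cv$class_decisions,
                       other_decisions = cv$other_decisions)
  }
  all_rp <- rbind(res$rp$class_decisions, res$rp$other_decisions)
  all_hl <- rbind(res$hilic$class_decisions, res$hilic$other_decisions)
  common <- intersect(all_rp$sample_id, all_hl$sample_id)
  fused <- serialFusion(all_rp[all_rp$sample_id %in% common, ],
                        all_hl[all_hl$sample_id %in% common, ])
  truth_pos <- fused$sample_id %in% res$rp$class_decisions$sample_id
  res$fused <- fused
  res$fused_confusion <- confusionSummary(
    tp = sum(fused$accepted & truth_pos), fn = sum(!fused$accepted & truth_pos),
    tn = sum(!fused$accepted & !truth_pos), fp = sum(fused$accepted & !truth_pos))
  if (!is.null(cfg$output_dir)) writeUrineReport(res, cfg)
  res
}

writeUrineReport <- function(res, cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- cfg$output_dir
  for (key in c("rp", "hilic")) {
    r <- res[[key]]
    write.csv(rbind(r$class_decisions, r$other_decisions),
              file.path(od, paste0("decisions_", key, ".csv")),
              row.names = FALSE)
    write.csv(r$model@rmsecv_curve,
              file.path(od, paste0("rmsecv_", key, ".csv")), row.names = FALSE)
    write.csv(data.frame(feature_id = names(r$model@dp), dp = r$model@dp,
                         selected = names(r$model@dp) %in%
                           r$model@selected_features),
              file.path(od, paste0("dp_", key, ".csv")), row.names = FALSE)
    grDevices::png(file.path(od, paste0("t2q_", key, ".png")), 700, 600)
    dec <- rbind(r$class_decisions, r$other_decisions)
    grp <- c(rep(1, nrow(r$class_decisions)), rep(2, nrow(r$other_decisions)))
    graphics::plot(dec$reduced_t2, dec$reduced_q, col = grp, pch = 19,
                   xlab = "reduced T2", ylab = "reduced Q",
                   main = paste("T2 vs Q,", toupper(key)))
    th <- seq(0, pi / 2, length.out = 100)
    graphics::lines(r$model@distance_limit * cos(th),
                    r$model@distance_limit * sin(th), lty = 2, col = 2)
    grDevices::dev.off()
  }
  write.csv(res$fused, file.path(od, "decisions_fused.csv"),
            row.names = FALSE)
  conf <- res$fused_confusion
  writeLines(c("# Urine pipeline report",
               sprintf("fused: tp=%d fn=%d tn=%d fp=%d (sens %d%%, spec %d%%)",
                       conf@tp, conf@fn, conf@tn, conf@fp,
                       percentHalfUp(sensitivity(conf)),
                       percentHalfUp(specificity(conf))),
               unlist(res$log)),
             file.path(od, "report.md"))
  invisible(od)
}

#' Run the in vitro exploration pipeline
#'
#' Total-area normalization, duplicate averaging, control-mean
#' subtraction, removal of treatment-related features (exclusion list),
#' scaling and PCA, returning scores, loadings and the explained-
#' variance table.
#'
#' @param config a [validateConfig()] list with `mode = "invitro"`.
#' @param table a [PeakTable-class] (or set `config$table_path` /
#'   `config$metadata_path`).
#' @param exclusions optional [exclusionList()] of treatment-related
#'   signals.
#' @return list with the processed `table`, `model`
#'   ([LatentModel-class]), `scores`, `explained` and the stage `log`.
#' @export
runInvitroPipeline <- function(config, table = NULL, exclusions = NULL) {
  cfg <- validateConfig(config)
  if (is.null(table))
    table <- readPeakTable(cfg$table_path, cfg$metadata_path, mode = "RP")
  log <- character()
  log <- stageLog(log, "input", table)
  table <- normalizeTotalArea(table)
  log <- stageLog(log, "normalize_total_area", table)
  scr <- screenReplicates(table, cfg$confidence)
  table <- scr$table
  log <- stageLog(log, "replicate_average", table)
  ctrl <- runInfo(table)$sample_id[runInfo(table)$group %in% cfg$control_group]
  table <- subtractControlMean(table, unique(ctrl))
  log <- stageLog(log, "subtract_control", table)
  if (!is.null(exclusions)) {
    hits <- matchExclusions(table, exclusions)
    if (length(hits)) {
      table <- dropFeatures(table, hits)
      log <- stageLog(log, "drop_excluded", table)
    }
  }
  scaled <- applyScaling(table, fitScaling(table, cfg$scaling))
  model <- fitPCA(scaled, K = cfg$K, confidence = cfg$confidence)
  pr <- projectRuns(model, scaled)
  out <- list(table = table, model = model, scores = pr$scores,
              diagnostics = pr$diagnostics,
              explained = data.frame(K = seq_len(model@K),
                                     fraction = explainedVariance(model)),
              log = log)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cbind(sample_id = runInfo(table)$sample_id,
                    as.data.frame(pr$scores)),
              file.path(cfg$output_dir, "scores.csv"), row.names = FALSE)
    write.csv(out$explained, file.path(cfg$output_dir, "explained.csv"),
              row.names = FALSE)
  }
  out
}
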