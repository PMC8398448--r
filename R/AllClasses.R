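#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median qf qchisq qnorm quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head modifyList
NULL

REQUIRED_RUN_COLS <- c("run_id", "sample_id", "replicate_index", "batch",
                       "injection_order", "role", "group")
RUN_ROLES   <- c("study", "qc", "blank", "pool")
CHROM_MODES <- c(RP = 12, HILIC = 9)   # run length in minutes per mode

#' PeakTable: the pipeline's single data currency
#'
#' A `PeakTable` couples a non-negative matrix of integrated chromatographic
#' peak areas with the descriptors of its runs (injections) and features
#' (m/z, retention-time pairs). It extends
#' [SummarizedExperiment::SummarizedExperiment] with features as rows and
#' runs as columns; [intensities()] returns the runs-by-features orientation
#' used throughout the preprocessing operations. Every transformation
#' appends a tag to the table's provenance, so a processed table carries a
#' complete record of how it was produced.
#'
#' @slot .
#' @name PeakTable-class
#' @aliases PeakTable-class
#' @exportClass PeakTable
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("mz", "rt", "mode") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz', 'rt', 'mode'")
  if (!all(REQUIRED_RUN_COLS %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:",
                        paste(REQUIRED_RUN_COLS, collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (nrow(object) > 0) {
    if (!all(rd$mode %in% names(CHROM_MODES)))
      msg <- c(msg, "feature mode must be 'RP' or 'HILIC'")
    if (any(rd$mz < 50 | rd$mz > 1000))
      msg <- c(msg, "feature m/z outside the acquisition scan range [50, 1000]")
    rtmax <- unname(CHROM_MODES[as.character(rd$mode)])
    if (any(rd$rt < 0 | rd$rt > rtmax))
      msg <- c(msg, "feature rt outside [0, run length] for its mode")
  }
  if (ncol(object) > 0) {
    if (!all(cd$role %in% RUN_ROLES))
      msg <- c(msg, "run role must be one of study/qc/blank/pool")
    st <- cd$role == "study"
    if (anyDuplicated(paste(cd$sample_id[st], cd$replicate_index[st])))
      msg <- c(msg, "(sample_id, replicate_index) must be unique among study runs")
    if (anyDuplicated(paste(cd$batch, cd$injection_order)))
      msg <- c(msg, "injection_order must be unique within batch")
  }
  a <- SummarizedExperiment::assay(object)
  # negative intensities are only legal after an explicit scaling transform
  if (length(a) && min(a) < 0 &&
      !any(grepl("^(scale:|log10|subtract_control)", provenance(object))))
    msg <- c(msg, "negative intensities in an unscaled table")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakTable
#'
#' @param intensities numeric matrix, runs x features, non-negative peak
#'   areas (arbitrary units). Zero codes "not detected".
#' @param runInfo data.frame with one row per run and columns
#'   `run_id`, `sample_id`, `replicate_index`, `batch`, `injection_order`,
#'   `role` (study/qc/blank/pool) and `group`.
#' @param featureInfo data.frame with one row per feature and columns
#'   `feature_id`, `mz` (Da), `rt` (minutes), `mode` ("RP" or "HILIC").
#' @param provenance character vector of transformation tags already
#'   applied (empty for a raw table).
#' @return a validated [PeakTable-class] object.
#' @export
PeakTable <- function(intensities, runInfo, featureInfo,
                      provenance = character()) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == nrow(runInfo),
            ncol(intensities) == nrow(featureInfo))
  a <- t(intensities)
  rownames(a) <- as.character(featureInfo$feature_id)
  colnames(a) <- as.character(runInfo$run_id)
  rd <- S4Vectors::DataFrame(featureInfo[, setdiff(colnames(featureInfo),
                                                   "feature_id"), drop = FALSE],
                             row.names = rownames(a))
  cd <- S4Vectors::DataFrame(runInfo, row.names = colnames(a))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensities = a), rowData = rd, colData = cd,
    metadata = list(provenance = as.character(provenance)))
  new("PeakTable", se)
}

#' Scaling state fitted on a peak table
#'
#' Captures an optional log10 transform followed by per-feature centering
#' and scaling (mean centering, Pareto scaling, or autoscaling), so the
#' identical transformation can be applied to new runs.
#'
#' @name ScalingState-class
#' @exportClass ScalingState
setClass("ScalingState",
  representation(method = "character", center = "numeric", scale = "numeric",
                 log10_applied = "logical", epsilon = "numeric",
                 feature_ids = "character"))

setValidity("ScalingState", function(object) {
  msg <- character()
  if (!object@method %in% c("center", "pareto", "autoscale"))
    msg <- c(msg, "method must be center/pareto/autoscale")
  n <- length(object@feature_ids)
  if (length(object@center) != n || length(object@scale) != n)
    msg <- c(msg, "center/scale vectors must match feature_ids length")
  if (any(object@scale < 0)) msg <- c(msg, "scale entries must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A fitted principal-component model
#'
#' Center/scale vectors, orthonormal loadings, per-component variances and
#' the Hotelling T-squared and Q-residual critical limits at the model's
#' confidence level.
#'
#' @name LatentModel-class
#' @exportClass LatentModel
setClass("LatentModel",
  representation(scaling = "ScalingState", loadings = "matrix",
                 component_variances = "numeric", total_variance = "numeric",
                 K = "integer", training_scores = "matrix",
                 t2_limit = "numeric", q_limit = "numeric",
                 confidence = "numeric", n_train = "integer"))

setValidity("LatentModel", function(object) {
  msg <- character()
  K <- object@K
  if (K < 1L) msg <- c(msg, "K must be >= 1")
  if (ncol(object@loadings) != K) msg <- c(msg, "loadings must have K columns")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(K))) > 1e-8)
    msg <- c(msg, "loadings are not orthonormal")
  if (is.unsorted(rev(object@component_variances)))
    msg <- c(msg, "component variances must be non-increasing")
  ev <- object@component_variances / object@total_variance
  if (any(ev < 0) || sum(ev) > 1 + 1e-9)
    msg <- c(msg, "explained-variance fractions outside [0, 1]")
  if (object@confidence <= 0 || object@confidence >= 1)
    msg <- c(msg, "confidence must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' A one-class SIMCA model
#'
#' A principal-component model of the target class restricted to the
#' features that survived discriminant-power selection, together with the
#' acceptance limit on the combined reduced T-squared / Q distance and the
#' cross-validation error curve used to choose the model order.
#'
#' @name ClassModel-class
#' @exportClass ClassModel
setClass("ClassModel",
  representation(target_class = "character", selected_features = "character",
                 dp = "numeric", dp_threshold = "numeric",
                 scaling = "ScalingState", inner = "LatentModel",
                 K = "integer", distance_limit = "numeric",
                 rmsecv_curve = "data.frame", confidence = "numeric"))

setValidity("ClassModel", function(object) {
  msg <- character()
  if (!all(object@selected_features %in% names(object@dp)))
    msg <- c(msg, "selected features must have discriminant powers")
  if (!identical(object@selected_features, object@scaling@feature_ids))
    msg <- c(msg, "scaling must cover exactly the selected features")
  dpsel <- object@dp[object@selected_features]
  if (length(dpsel) && any(dpsel <= object@dp_threshold))
    msg <- c(msg, "all selected features must exceed the dp threshold")
  if (object@distance_limit < 0) msg <- c(msg, "distance limit must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Confusion counts for a one-class decision rule
#'
#' @name ConfusionSummary-class
#' @exportClass ConfusionSummary
setClass("ConfusionSummary",
  representation(tp = "integer", fn = "integer", tn = "integer", fp = "integer"))

setValidity("ConfusionSummary", function(object) {
  if (any(c(object@tp, object@fn, object@tn, object@fp) < 0))
    "counts must be non-negative" else TRUE
})

#' Construct a confusion summary from counts
#'
#' @param tp,fn,tn,fp non-negative integer counts: class runs accepted /
#'   rejected, out-of-class runs rejected / accepted.
#' @return a [ConfusionSummary-class] object.
#' @export
confusionSummary <- function(tp, fn, tn, fp) {
  new("ConfusionSummary", tp = as.integer(tp), fn = as.integer(fn),
      tn = as.integer(tn), fp = as.integer(fp))
}
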