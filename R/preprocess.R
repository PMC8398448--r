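#' @include AllGenerics.R
NULL

#' Remove sparsely detected features
#'
#' Drops every feature detected (nonzero) in fewer than `min_fraction` of
#' the non-blank runs; a feature detected in exactly the threshold
#' fraction is retained. The default reproduces the 15% detection rule
#' applied to the 7000-feature vendor exports, which typically removes
#' more than half of the features of an untargeted urine table.
#'
#' @param table a [PeakTable-class].
#' @param min_fraction minimum detected fraction, in (0, 1].
#' @param keep feature ids exempt from the filter (e.g. a spiked internal
#'   standard that only appears in QC injections).
#' @return the filtered table, provenance tagged.
#' @export
filterSparse <- function(table, min_fraction = 0.15, keep = character()) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (nRuns(table) == 0L || nFeatures(table) == 0L)
    stop("cannot sparsity-filter an empty table")
  m <- intensities(table)
  denom <- runInfo(table)$role != "blank"
  frac <- colMeans(m[denom, , drop = FALSE] > 0)
  keep <- rownames(table)[frac >= min_fraction | rownames(table) %in% keep]
  subsetFeatures(table, keep,
                 tag = sprintf("filter_sparse(min_fraction=%g)", min_fraction))
}

#' Normalize each run to unit total area
#'
#' Divides every intensity by the total area of its run's chromatogram,
#' so each row of the intensity matrix sums to one. Used for the
#' intrinsically homogeneous in vitro tables.
#'
#' @param table a [PeakTable-class].
#' @return the normalized table.
#' @export
normalizeTotalArea <- function(table) {
  m <- intensities(table)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("zero total area in run(s): ",
         paste(rownames(m)[tot <= 0], collapse = ", "))
  setIntensities(table, m / tot, "normalize_total_area")
}

# internal: assign each run to the most recent preceding run among `anchors`
# within its batch (falling back to the first anchor of the batch)
assignAnchors <- function(ri, anchors) {
  idx <- integer(nrow(ri))
  for (b in unique(ri$batch)) {
    inb <- which(ri$batch == b)
    anc <- inb[anchors[inb]]
    if (!length(anc)) stop("batch ", b, " has no QC/pool run")
    anc_order <- ri$injection_order[anc]
    for (i in inb) {
      ok <- anc_order <= ri$injection_order[i]
      idx[i] <- if (any(ok)) anc[ok][which.max(anc_order[ok])]
                else anc[which.min(anc_order)]
    }
  }
  idx
}

#' Batch normalization from an internal-standard feature
#'
#' Implements the QC-ratio correction used for reverse-phase batches: the
#' mean internal-standard (e.g. fentanyl-D5) area over all QC runs is
#' computed; each QC run's ratio to that mean becomes its correction
#' factor; and every run is divided by the factor of its assigned QC (the
#' nearest preceding QC in injection order within its batch).
#'
#' @param table a [PeakTable-class] with `role = "qc"` runs.
#' @param is_feature feature id of the internal standard.
#' @return the corrected table.
#' @export
normalizeInternalStandard <- function(table, is_feature) {
  stopifnot(is_feature %in% rownames(table))
  ri <- runInfo(table)
  m <- intensities(table)
  qc <- ri$role == "qc"
  if (!any(qc)) stop("no QC runs in table")
  for (b in unique(ri$batch))
    if (!any(qc & ri$batch == b)) stop("batch ", b, " has no QC run")
  is_area <- m[, is_feature]
  if (any(is_area[qc] <= 0))
    stop("zero internal-standard area in QC run(s): ",
         paste(ri$run_id[qc & is_area <= 0], collapse = ", "))
  f <- is_area / mean(is_area[qc])          # per-QC correction factor
  anchor <- assignAnchors(ri, qc)
  corr <- f[anchor]
  setIntensities(table, m / corr,
                 sprintf("normalize_internal_standard(%s)", is_feature))
}

#' Batch normalization from pooled-sample profiles
#'
#' Implements the pool-ratio correction used for HILIC batches: each
#' pool run's mean intensity over features, divided by the grand mean over
#' all pool runs, becomes its correction factor; every run is divided by
#' the factor of its assigned pool run (nearest preceding within batch).
#'
#' @param table a [PeakTable-class] with `role = "pool"` runs.
#' @return the corrected table.
#' @export
normalizePoolProfile <- function(table) {
  ri <- runInfo(table)
  m <- intensities(table)
  pool <- ri$role == "pool"
  if (!any(pool)) stop("no pool runs in table")
  for (b in unique(ri$batch))
    if (!any(pool & ri$batch == b)) stop("batch ", b, " has no pool run")
  prof <- rowMeans(m)                        # per-run mean over features
  f <- prof / mean(prof[pool])
  anchor <- assignAnchors(ri, pool)
  corr <- f[anchor]
  setIntensities(table, m / corr, "normalize_pool_profile")
}

#' Log10-transform intensities
#'
#' Applies `x -> log10(x + eps)` with `eps` equal to the smallest nonzero
#' intensity in the table, so zero-coded non-detections map to the
#' table's detection floor rather than to -Inf.
#'
#' @param table a [PeakTable-class] with non-negative intensities.
#' @return the transformed table; `eps` is recorded in provenance.
#' @export
log10Transform <- function(table) {
  m <- intensities(table)
  nz <- m[m > 0]
  if (!length(nz)) stop("cannot log-transform an all-zero table")
  eps <- min(nz)
  setIntensities(table, log10(m + eps), sprintf("log10(eps=%.8g)", eps))
}

#' Fit and apply per-feature centering and scaling
#'
#' `fitScaling()` learns per-feature means and scale factors on a table;
#' `applyScaling()` applies a fitted state to a table with the identical
#' feature set (the training table or new runs). Methods: `center`
#' subtracts the mean; `pareto` additionally divides by the square root
#' of the standard deviation; `autoscale` divides by the standard
#' deviation. Standard deviations use the n-1 denominator. Constant
#' features get a zero scale entry and pass through as all-zeros.
#'
#' @param table a [PeakTable-class].
#' @param method one of "center", "pareto", "autoscale".
#' @return `fitScaling`: a [ScalingState-class]; `applyScaling`: the
#'   scaled table.
#' @export
fitScaling <- function(table, method = c("center", "pareto", "autoscale")) {
  method <- match.arg(method)
  m <- intensities(table)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sc <- switch(method, center = rep(1, ncol(m)), pareto = sqrt(sdv),
               autoscale = sdv)
  sc[!is.finite(sc)] <- 0
  new("ScalingState", method = method, center = mu, scale = sc,
      log10_applied = any(grepl("^log10", provenance(table))),
      epsilon = NA_real_, feature_ids = colnames(m))
}

#' @rdname fitScaling
#' @param state a [ScalingState-class] from `fitScaling()`.
#' @export
applyScaling <- function(table, state) {
  if (!identical(colnames(intensities(table)), state@feature_ids))
    stop("feature set differs from the one the scaling was fitted on")
  m <- scaleMatrix(intensities(table), state)
  setIntensities(table, m, sprintf("scale:%s", state@method))
}

# internal: the matrix-level scaling used by models (constant features -> 0)
scaleMatrix <- function(m, state) {
  m <- sweep(m, 2, state@center)
  s <- state@scale
  pos <- s > 0
  m[, pos] <- sweep(m[, pos, drop = FALSE], 2, s[pos], "/")
  m[, !pos] <- 0
  m
}

#' Subtract the mean control profile
#'
#' Removes the contribution common to all samples (e.g. the HepG2
#' cell-line background in the in vitro study) by subtracting the
#' feature-wise mean over the control runs from every run, controls
#' included.
#'
#' @param table a [PeakTable-class].
#' @param control_ids sample ids of the control runs.
#' @return the centered table.
#' @export
subtractControlMean <- function(table, control_ids) {
  ri <- runInfo(table)
  unknown <- setdiff(control_ids, ri$sample_id)
  if (length(control_ids) == 0L || length(unknown))
    stop("unknown or empty control sample id(s): ",
         paste(unknown, collapse = ", "))
  m <- intensities(table)
  ctrl <- ri$sample_id %in% control_ids
  mu <- colMeans(m[ctrl, , drop = FALSE])
  setIntensities(table, sweep(m, 2, mu), "subtract_control")
}

#' Drop named features from a table
#'
#' @param table a [PeakTable-class].
#' @param feature_ids ids to remove; all must exist.
#' @return the reduced table; retained intensities are untouched.
#' @export
dropFeatures <- function(table, feature_ids) {
  unknown <- setdiff(feature_ids, rownames(table))
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(rownames(table), feature_ids)
  subsetFeatures(table, keep,
                 tag = sprintf("drop_features(n=%d)", length(feature_ids)))
}
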