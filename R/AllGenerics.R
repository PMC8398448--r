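#' @include AllClasses.R
NULL

#' Accessors for PeakTable and model objects
#'
#' `intensities()` returns the runs-by-features intensity matrix,
#' `runInfo()` and `featureInfo()` the run and feature descriptor tables,
#' and `provenance()` the ordered list of transformation tags applied to a
#' table since it was read or generated.
#'
#' @param x a [PeakTable-class] (or, for `provenance`, any object carrying
#'   provenance metadata).
#' @return `intensities`: numeric matrix (runs x features); `runInfo`,
#'   `featureInfo`: data.frames; `provenance`: character vector;
#'   `nRuns`, `nFeatures`: integers.
#' @name peaktable-accessors
#' @aliases intensities runInfo featureInfo provenance nRuns nFeatures
NULL

#' @rdname peaktable-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname peaktable-accessors
#' @export
setGeneric("runInfo", function(x) standardGeneric("runInfo"))
#' @rdname peaktable-accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
#' @rdname peaktable-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname peaktable-accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))
#' @rdname peaktable-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname peaktable-accessors
setMethod("intensities", "PeakTable", function(x) {
  t(SummarizedExperiment::assay(x, "intensities"))
})
#' @rdname peaktable-accessors
setMethod("runInfo", "PeakTable", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})
#' @rdname peaktable-accessors
setMethod("featureInfo", "PeakTable", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(feature_id = if (is.null(rownames(x))) character() else rownames(x),
             rd, stringsAsFactors = FALSE, row.names = NULL)
})
#' @rdname peaktable-accessors
setMethod("provenance", "PeakTable", function(x) {
  pv <- S4Vectors::metadata(x)$provenance
  if (is.null(pv)) character() else pv
})
#' @rdname peaktable-accessors
setMethod("nRuns", "PeakTable", function(x) ncol(x))
#' @rdname peaktable-accessors
setMethod("nFeatures", "PeakTable", function(x) nrow(x))

# internal: return a copy with a provenance tag appended and (optionally)
# a new intensity matrix (runs x features)
setIntensities <- function(x, m, tag) {
  a <- t(m)
  dimnames(a) <- dimnames(SummarizedExperiment::assay(x))
  SummarizedExperiment::assay(x, "intensities", withDimnames = FALSE) <- a
  S4Vectors::metadata(x)$provenance <- c(provenance(x), tag)
  validObject(x)
  x
}

# internal: subset features by id, preserving order of `ids`
subsetFeatures <- function(x, ids, tag = NULL) {
  stopifnot(all(ids %in% rownames(x)))
  out <- x[ids, ]
  if (!is.null(tag))
    S4Vectors::metadata(out)$provenance <- c(provenance(x), tag)
  out
}

#' @describeIn PeakTable-class compact display with provenance
#' @param object a PeakTable
#' @export
setMethod("show", "PeakTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("PeakTable: %d runs x %d features (%s)\n",
              ncol(object), nrow(object),
              paste(unique(SummarizedExperiment::rowData(object)$mode),
                    collapse = "/")))
  cat("  roles:", paste(sprintf("%s=%d", names(table(cd$role)),
                                table(cd$role)), collapse = " "), "\n")
  pv <- provenance(object)
  cat("  provenance:", if (length(pv)) paste(pv, collapse = " -> ")
      else "(raw)", "\n")
})

#' @describeIn LatentModel-class compact display
#' @param object a LatentModel
#' @export
setMethod("show", "LatentModel", function(object) {
  ev <- 100 * object@component_variances / object@total_variance
  cat(sprintf("LatentModel: K=%d, n=%d, %d features\n", object@K,
              object@n_train, nrow(object@loadings)))
  cat(sprintf("  explained variance: %s (cum %.1f%%)\n",
              paste(sprintf("%.1f%%", ev), collapse = " "), sum(ev)))
  cat(sprintf("  limits (%.0f%%): T2=%.3f  Q=%.4g\n",
              100 * object@confidence, object@t2_limit, object@q_limit))
})

#' @describeIn ClassModel-class compact display
#' @param object a ClassModel
#' @export
setMethod("show", "ClassModel", function(object) {
  cat(sprintf("One-class SIMCA model for '%s'\n", object@target_class))
  cat(sprintf("  %d selected features (dp > %g), K=%d, acceptance d <= %.4f\n",
              length(object@selected_features), object@dp_threshold,
              object@K, object@distance_limit))
})

#' @describeIn ConfusionSummary-class display counts and half-up percentages
#' @param object a ConfusionSummary
#' @export
setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf("ConfusionSummary: tp=%d fn=%d tn=%d fp=%d\n",
              object@tp, object@fn, object@tn, object@fp))
  cat(sprintf("  sensitivity %d%%  specificity %d%%\n",
              percentHalfUp(sensitivity(object)),
              percentHalfUp(specificity(object))))
})

#' Sensitivity and specificity of a confusion summary
#'
#' @param x a [ConfusionSummary-class].
#' @return a proportion in `[0, 1]`.
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname sensitivity
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname sensitivity
setMethod("sensitivity", "ConfusionSummary",
          function(x) x@tp / (x@tp + x@fn))
#' @rdname sensitivity
setMethod("specificity", "ConfusionSummary",
          function(x) x@tn / (x@tn + x@fp))

#' Round a proportion to an integer percentage, halves up
#'
#' Reproduces the reporting convention in which 23/24 prints as 96% and
#' 42/57 as 74%: the proportion is multiplied by 100 and rounded with ties
#' going away from zero (half-up), unlike [round()]'s round-half-even.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @return integer percentage(s).
#' @export
percentHalfUp <- function(p) as.integer(floor(100 * p + 0.5))
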