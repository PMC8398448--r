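#' @include AllGenerics.R
NULL

#' Read a wide-format peak table and its run metadata
#'
#' Reads a vendor-style wide export: one row per feature with leading
#' `mz` and `rt` columns (optionally preceded by `feature_id` and followed
#' by `mode`), then one intensity column per chromatographic run. Run
#' metadata comes from a separate CSV keyed by `run_id`. A provenance
#' sidecar (`<path>.provenance.json`) written by [writePeakTable()] is
#' restored when present.
#'
#' @param path peak-table CSV/TSV (separator auto-detected from the
#'   extension, "." decimal separator).
#' @param metadata_path run-metadata CSV with columns `run_id`,
#'   `sample_id`, `replicate_index`, `batch`, `injection_order`, `role`,
#'   `group`.
#' @param mode chromatographic mode of the table ("RP" or "HILIC"); used
#'   when the file has no `mode` column.
#' @param columns optional named list remapping non-standard headers,
#'   e.g. `list(mz = "Mass", rt = "RT")`.
#' @return a validated [PeakTable-class].
#' @details Hard errors: an intensity column with no metadata row (the
#'   orphan run is named), negative intensities, and duplicated features
#'   (m/z within 1e-6 Da and rt within 1e-3 min of another row).
#' @export
readPeakTable <- function(path, metadata_path, mode = "RP", columns = list()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  for (std in intersect(names(columns), c("feature_id", "mz", "rt", "mode")))
    names(tab)[names(tab) == columns[[std]]] <- std
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_RUN_COLS, colnames(meta))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))

  lead <- intersect(c("feature_id", "mz", "rt", "mode"), colnames(tab))
  if (!all(c("mz", "rt") %in% lead))
    stop("peak table must have 'mz' and 'rt' columns")
  tab$mz <- as.numeric(tab$mz)
  tab$rt <- as.numeric(tab$rt)
  run_cols <- setdiff(colnames(tab), lead)
  orphan <- setdiff(run_cols, meta$run_id)
  if (length(orphan))
    stop("run(s) absent from metadata: ", paste(orphan, collapse = ", "))
  meta <- meta[match(run_cols, meta$run_id), , drop = FALSE]

  m <- as.matrix(tab[, run_cols, drop = FALSE])
  if (length(m) && min(m) < 0)
    stop("negative intensities in ", path)
  if (nrow(tab) > 1) {
    o <- order(tab$mz, tab$rt)
    dmz <- diff(tab$mz[o]); drt <- abs(diff(tab$rt[o]))
    if (any(dmz <= 1e-6 & drt <= 1e-3))
      stop("duplicate feature rows (mz within 1e-6, rt within 1e-3)")
  }
  fi <- data.frame(
    feature_id = if ("feature_id" %in% lead) as.character(tab$feature_id)
                 else sprintf("F%05d", seq_len(nrow(tab))),
    mz = tab$mz, rt = tab$rt,
    mode = if ("mode" %in% lead) as.character(tab$mode) else mode,
    stringsAsFactors = FALSE)
  prov <- character()
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    prov <- as.character(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  PeakTable(t(m), meta, fi, provenance = prov)
}

#' Write a peak table and its provenance sidecar
#'
#' Emits the wide CSV format read by [readPeakTable()] (columns
#' `feature_id`, `mz`, `rt`, `mode`, then one column per run), plus
#' `<path>.provenance.json` recording the transformation chain. Run
#' metadata is written to `metadata_path` when supplied.
#'
#' @param table a [PeakTable-class].
#' @param path output CSV path.
#' @param metadata_path optional path for the run-metadata CSV.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(table, path, metadata_path = NULL) {
  fi <- featureInfo(table)
  m <- intensities(table)
  out <- cbind(fi[, c("feature_id", "mz", "rt", "mode")],
               as.data.frame(t(m), check.names = FALSE))
  ok <- tryCatch(write.csv(out, path, row.names = FALSE), error = identity)
  if (inherits(ok, "error")) stop("cannot write peak table to ", path)
  jsonlite::write_json(provenance(table), paste0(path, ".provenance.json"))
  if (!is.null(metadata_path))
    write.csv(runInfo(table), metadata_path, row.names = FALSE)
  invisible(path)
}

#' Exclusion lists of known drug-related signals
#'
#' An exclusion list names m/z values (optionally with a retention time)
#' of parent drugs and their direct metabolites so that they can be
#' removed from the feature space before modelling; the classifier is
#' meant to see only the indirect metabolic fingerprint.
#'
#' @param mz numeric vector of m/z values (Da).
#' @param rt numeric vector of retention times (min), `NA` where the entry
#'   matches at any rt.
#' @param label non-empty character labels.
#' @param mz_tol_ppm m/z matching tolerance in ppm (default 5, the mass
#'   alignment tolerance of the upstream processing).
#' @param rt_tol_min rt matching tolerance in minutes (default 0.5, the
#'   rt alignment tolerance).
#' @return an `ExclusionList` (classed data.frame with tolerance
#'   attributes).
#' @export
exclusionList <- function(mz, rt = NA_real_, label,
                          mz_tol_ppm = 5, rt_tol_min = 0.5) {
  stopifnot(mz_tol_ppm > 0, rt_tol_min >= 0, all(nzchar(label)))
  df <- data.frame(mz = mz, rt = rt, label = label, stringsAsFactors = FALSE)
  attr(df, "mz_tol_ppm") <- mz_tol_ppm
  attr(df, "rt_tol_min") <- rt_tol_min
  class(df) <- c("ExclusionList", "data.frame")
  df
}

#' @rdname exclusionList
#' @param path CSV with columns `mz`, `rt` (optional), `label`.
#' @export
readExclusionList <- function(path, mz_tol_ppm = 5, rt_tol_min = 0.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  exclusionList(df$mz,
                if ("rt" %in% colnames(df)) df$rt else NA_real_,
                df$label, mz_tol_ppm = mz_tol_ppm, rt_tol_min = rt_tol_min)
}

#' Match features of a table against an exclusion list
#'
#' A feature matches an entry when its m/z lies within `mz_tol_ppm`
#' (relative to the entry's m/z) and, for entries that carry a retention
#' time, its rt lies within `rt_tol_min`. Both comparisons include the
#' boundary. Enlarging either tolerance can only grow the matched set.
#'
#' @param table a [PeakTable-class].
#' @param excl an [exclusionList()].
#' @return character vector of matched feature ids (table order).
#' @export
matchExclusions <- function(table, excl) {
  if (nrow(excl) == 0L || nFeatures(table) == 0L) return(character())
  fi <- featureInfo(table)
  ppm <- attr(excl, "mz_tol_ppm")
  rtt <- attr(excl, "rt_tol_min")
  hit <- rep(FALSE, nrow(fi))
  for (k in seq_len(nrow(excl))) {
    dm <- abs(fi$mz - excl$mz[k]) <= excl$mz[k] * ppm * 1e-6
    if (!is.na(excl$rt[k])) dm <- dm & abs(fi$rt - excl$rt[k]) <= rtt
    hit <- hit | dm
  }
  fi$feature_id[hit]
}
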