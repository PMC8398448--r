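#' @include latent_models.R
NULL

# internal: centering-only state for a matrix
centerState <- function(m) {
  new("ScalingState", method = "center", center = colMeans(m),
      scale = rep(1, ncol(m)), log10_applied = FALSE, epsilon = NA_real_,
      feature_ids = colnames(m))
}

# internal: per-feature mean squared residual of rows of `m` under a
# K-component centered PCA fitted on `train`
residualMS <- function(train, m, K) {
  st <- centerState(train)
  xs <- scaleMatrix(train, st)
  sv <- svd(xs, nu = 0, nv = K)
  V <- sv$v
  xh <- scaleMatrix(m, st)
  r <- xh - xh %*% V %*% t(V)
  colMeans(r^2)
}

#' Discriminant power of each feature for a one-class model
#'
#' For a K-component model of the target class, the discriminant power of
#' feature j is `dp_j = sqrt(s2_out_j / s2_in_j)`: the ratio of the mean
#' squared residual of out-of-class runs under the class model to the
#' cross-validated mean squared residual of the class's own runs
#' (leave-one-out for class sizes up to 30, venetian-blinds 10-fold
#' otherwise). Cross-validating the in-class residual avoids the
#' deflation a self-fitted residual would cause. Features that the class
#' model reconstructs perfectly (`s2_in = 0`) get `dp = Inf`.
#'
#' A feature uninformative for the class contrast has dp near 1; planted
#' out-of-class displacements drive dp far above 1.
#'
#' @param class_table runs of the target class ([PeakTable-class]),
#'   scaled as the model will be.
#' @param other_table out-of-class runs sharing the feature set.
#' @param K class-model order; must satisfy `K < n_class - 1`.
#' @return named numeric vector of discriminant powers (>= 0).
#' @export
discriminantPower <- function(class_table, other_table, K) {
  mc <- intensities(class_table)
  mo <- intensities(other_table)
  if (!identical(colnames(mc), colnames(mo)))
    stop("class and out-of-class tables must share features")
  n <- nrow(mc)
  if (K >= n - 1L) stop("K must be < class size - 1")
  s2_out <- residualMS(mc, mo, K)

  folds <- if (n <= 30) n else 10L
  fold <- venetianFolds(n, folds)
  s2_in_acc <- matrix(0, n, ncol(mc))
  for (f in seq_len(folds)) {
    held <- fold == f
    st <- centerState(mc[!held, , drop = FALSE])
    xs <- scaleMatrix(mc[!held, , drop = FALSE], st)
    V <- svd(xs, nu = 0, nv = K)$v
    xh <- scaleMatrix(mc[held, , drop = FALSE], st)
    s2_in_acc[held, ] <- (xh - xh %*% V %*% t(V))^2
  }
  s2_in <- colMeans(s2_in_acc)
  dp <- sqrt(s2_out / s2_in)
  dp[s2_in == 0] <- Inf
  names(dp) <- colnames(mc)
  dp
}

#' Select features by discriminant-power threshold
#'
#' Returns, in table order, the features with `dp` strictly greater than
#' `threshold`. Raising the threshold can only shrink the selection.
#'
#' @param dp named discriminant-power vector from [discriminantPower()].
#' @param threshold non-negative cut-off (e.g. 1.5 for the reverse-phase
#'   model, 4.5 for HILIC).
#' @return character vector of selected feature ids.
#' @export
selectVariables <- function(dp, threshold) {
  stopifnot(threshold >= 0)
  names(dp)[dp > threshold]
}

# internal: refit scaling + PCA on class rows of a raw (unscaled-by-class)
# matrix restricted to selected features
fitInner <- function(m, K, confidence, method, cap_rank = FALSE) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sc <- switch(method, center = rep(1, ncol(m)), pareto = sqrt(sdv),
               autoscale = sdv)
  sc[!is.finite(sc)] <- 0
  st <- new("ScalingState", method = method, center = mu, scale = sc,
            log10_applied = FALSE, epsilon = NA_real_,
            feature_ids = colnames(m))
  fitPCAMatrix(m, K, confidence, st, cap_rank = cap_rank)
}

# internal: combined reduced distance of rows of `m` under a model
combinedDistance <- function(model, m) {
  d <- projectMatrix(model, m)$diagnostics
  cbind(d, distance = sqrt(d$reduced_t2^2 + d$reduced_q^2))
}

#' Fit a one-class SIMCA model with variable selection and RMSECV
#'
#' The full training procedure for one chromatographic mode: (1) fit the
#' class scaling (`method`) on the target-class runs and apply it to both
#' tables; (2) compute discriminant powers with a `dpK`-component class
#' model and keep features with `dp > dp_threshold`; (3) for every
#' candidate order K, run venetian-blinds cross-validation over the class
#' runs, refitting scaling and PCA without each fold, and record two
#' error curves — the classification form (root mean square of the
#' held-out distance shortfall `max(0, d - distance_limit)`) and the
#' reconstruction form (root mean squared residual); (4) pick the K
#' minimizing the classification RMSECV (ties to the smallest K) and
#' refit on all class runs.
#'
#' @param class_table target-class runs ([PeakTable-class], raw scale —
#'   scaling is fitted inside, class-referenced).
#' @param other_table out-of-class runs with the same features.
#' @param K_candidates candidate model orders (default 1:6).
#' @param dp_threshold discriminant-power cut-off.
#' @param method class scaling: "pareto" (default), "autoscale" or
#'   "center".
#' @param distance_limit acceptance limit on the combined reduced
#'   distance (default `sqrt(2)`).
#' @param confidence confidence level for the T2/Q limits (default 0.95).
#' @param dpK model order used inside [discriminantPower()] (default 4).
#' @param folds cross-validation folds (default 10).
#' @return a [ClassModel-class].
#' @export
fitSIMCA <- function(class_table, other_table, K_candidates = 1:6,
                     dp_threshold = 1.5, method = "pareto",
                     distance_limit = sqrt(2), confidence = 0.95,
                     dpK = 4, folds = 10) {
  n <- nRuns(class_table)
  if (n < max(K_candidates) + 2L)
    stop("class table needs at least max(K_candidates) + 2 runs")
  dpK <- min(dpK, n - 2L)
  sc_full <- fitScaling(class_table, method)
  dp <- discriminantPower(applyScaling(class_table, sc_full),
                          applyScaling(other_table, sc_full), K = dpK)
  sel <- selectVariables(dp, dp_threshold)
  if (!length(sel))
    stop("no feature exceeds dp_threshold = ", dp_threshold,
         "; decrease the threshold")

  mc <- intensities(class_table)[, sel, drop = FALSE]
  folds <- min(folds, n)
  fold <- venetianFolds(n, folds)
  rmsecv_class <- rmsecv_recon <- numeric(length(K_candidates))
  for (ki in seq_along(K_candidates)) {
    K <- K_candidates[ki]
    short2 <- q2 <- numeric(0)
    for (f in seq_len(folds)) {
      held <- fold == f
      mod <- fitInner(mc[!held, , drop = FALSE], K, confidence, method,
                      cap_rank = TRUE)
      d <- combinedDistance(mod, mc[held, , drop = FALSE])
      short2 <- c(short2, pmax(0, d$distance - distance_limit)^2)
      q2 <- c(q2, d$q)
    }
    rmsecv_class[ki] <- sqrt(mean(short2))
    rmsecv_recon[ki] <- sqrt(mean(q2))
  }
  chosen <- K_candidates[which.min(rmsecv_class)]   # ties: smallest K first
  inner <- fitInner(mc, chosen, confidence, method)
  new("ClassModel",
      target_class = as.character(unique(runInfo(class_table)$group))[1],
      selected_features = sel, dp = dp, dp_threshold = dp_threshold,
      scaling = inner@scaling, inner = inner, K = as.integer(chosen),
      distance_limit = distance_limit,
      rmsecv_curve = data.frame(K = K_candidates, rmsecv = rmsecv_class,
                                rmsecv_reconstruction = rmsecv_recon),
      confidence = confidence)
}

# internal: decisions for a plain matrix already restricted to selected
# features (raw scale)
decideMatrix <- function(model, m, sample_ids) {
  d <- combinedDistance(model@inner, m)
  data.frame(sample_id = sample_ids,
             reduced_t2 = d$reduced_t2, reduced_q = d$reduced_q,
             distance = d$distance,
             accepted = d$distance <= model@distance_limit,
             stringsAsFactors = FALSE)
}

#' Classify runs with a fitted one-class SIMCA model
#'
#' Projects each run into the class model's principal-component space and
#' accepts it as a class member when the combined reduced distance
#' `sqrt(reduced_t2^2 + reduced_q^2)` does not exceed the model's
#' acceptance limit (boundary inclusive).
#'
#' @param model a [ClassModel-class].
#' @param table a [PeakTable-class] containing all of the model's
#'   selected features.
#' @return data.frame with one row per run: `sample_id`, `reduced_t2`,
#'   `reduced_q`, `distance`, `accepted`.
#' @export
classifyRuns <- function(model, table) {
  missing <- setdiff(model@selected_features, rownames(table))
  if (length(missing))
    stop("table lacks selected feature(s): ",
         paste(head(missing, 5), collapse = ", "))
  m <- intensities(table)[, model@selected_features, drop = FALSE]
  decideMatrix(model, m, runInfo(table)$sample_id)
}

#' Cross-validated confusion summary of a one-class SIMCA model
#'
#' Class runs are scored by hold-out: venetian-blinds folds over the
#' class table, each run's decision coming from a model refitted (scaling
#' and PCA, fixed feature selection and order) without its fold.
#' Out-of-class runs are scored by projection onto the full model.
#'
#' @inheritParams fitSIMCA
#' @param model optionally, a pre-fitted [ClassModel-class] (otherwise
#'   [fitSIMCA()] is called with the remaining arguments).
#' @param ... passed to [fitSIMCA()].
#' @return list with `confusion` ([ConfusionSummary-class]),
#'   `class_decisions`, `other_decisions` and `model`.
#' @export
crossValidatedDecisions <- function(class_table, other_table, model = NULL,
                                    folds = 10, ...) {
  if (is.null(model))
    model <- fitSIMCA(class_table, other_table, folds = folds, ...)
  mc <- intensities(class_table)[, model@selected_features, drop = FALSE]
  n <- nrow(mc)
  folds <- min(folds, n)
  fold <- venetianFolds(n, folds)
  cls <- vector("list", folds)
  for (f in seq_len(folds)) {
    held <- fold == f
    sub <- fitInner(mc[!held, , drop = FALSE], model@K, model@confidence,
                    model@scaling@method, cap_rank = TRUE)
    subm <- model; subm@inner <- sub; subm@scaling <- sub@scaling
    cls[[f]] <- decideMatrix(subm, mc[held, , drop = FALSE],
                             runInfo(class_table)$sample_id[held])
  }
  class_dec <- do.call(rbind, cls)
  class_dec <- class_dec[match(runInfo(class_table)$sample_id,
                               class_dec$sample_id), ]
  other_dec <- classifyRuns(model, other_table)
  conf <- confusionSummary(tp = sum(class_dec$accepted),
                           fn = sum(!class_dec$accepted),
                           tn = sum(!other_dec$accepted),
                           fp = sum(other_dec$accepted))
  list(confusion = conf, class_decisions = class_dec,
       other_decisions = other_dec, model = model)
}

#' Serial fusion of reverse-phase and HILIC decisions
#'
#' Two-step decision rule: a sample is declared positive only if the
#' reverse-phase model accepts it AND the HILIC model accepts it; samples
#' negative in the first (RP) step are never re-evaluated. The fused
#' false-positive set is therefore the intersection of the two models'
#' false-positive sets, and can never exceed either.
#'
#' @param decisions_rp,decisions_hilic decision data.frames from
#'   [classifyRuns()] or [crossValidatedDecisions()], covering the same
#'   sample ids.
#' @return data.frame with `sample_id`, `accepted_rp`, `accepted_hilic`,
#'   `accepted`.
#' @export
serialFusion <- function(decisions_rp, decisions_hilic) {
  if (!setequal(decisions_rp$sample_id, decisions_hilic$sample_id) ||
      anyDuplicated(decisions_rp$sample_id) ||
      anyDuplicated(decisions_hilic$sample_id))
    stop("decision lists must cover the same sample ids exactly once")
  h <- decisions_hilic[match(decisions_rp$sample_id,
                             decisions_hilic$sample_id), ]
  data.frame(sample_id = decisions_rp$sample_id,
             accepted_rp = decisions_rp$accepted,
             accepted_hilic = h$accepted,
             accepted = decisions_rp$accepted & h$accepted,
             stringsAsFactors = FALSE)
}
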