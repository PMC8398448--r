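#' @include AllGenerics.R
NULL

# Jackson-Mudholkar critical limit for the Q residual, computed from the
# eigenvalues discarded by the model; falls back to chi-squared moment
# matching when the JM terms are degenerate.
qLimit <- function(lambda_disc, confidence) {
  lambda_disc <- lambda_disc[lambda_disc > 0]
  if (!length(lambda_disc)) return(0)
  th1 <- sum(lambda_disc); th2 <- sum(lambda_disc^2); th3 <- sum(lambda_disc^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  z <- qnorm(confidence)
  if (is.finite(h0) && h0 > 0) {
    base <- z * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2
    if (base > 0) return(th1 * base^(1 / h0))
  }
  g <- th2 / th1; h <- th1^2 / th2          # chi-squared moment matching
  g * qchisq(confidence, df = h)
}

t2Limit <- function(K, n, confidence) {
  K * (n - 1) * (n + 1) / (n * (n - K)) * qf(confidence, K, n - K)
}

# internal: PCA on a plain matrix with a fitted ScalingState; cap_rank
# silently reduces K to the numerical rank (used inside CV loops where a
# fold's scaled submatrix may be rank-deficient)
fitPCAMatrix <- function(m, K, confidence, scaling, cap_rank = FALSE) {
  n <- nrow(m); p <- ncol(m)
  if (K > min(n - 1L, p)) {
    if (!cap_rank)
      stop("K = ", K, " exceeds min(n_runs - 1, n_features) = ",
           min(n - 1L, p))
    K <- min(n - 1L, p)
  }
  xs <- scaleMatrix(m, scaling)
  sv <- svd(xs)
  lambda <- sv$d^2 / (n - 1)
  rank <- sum(lambda > 1e-12 * max(lambda[1], 1e-300))
  if (K > rank) {
    if (!cap_rank)
      stop("K = ", K, " exceeds the numerical rank of the training data")
    K <- rank
  }
  load <- sv$v[, seq_len(K), drop = FALSE]
  # deterministic sign: each loading's largest-magnitude entry is positive
  flip <- vapply(seq_len(K), function(k) {
    v <- load[, k]; sign(v[which.max(abs(v))])
  }, numeric(1))
  load <- sweep(load, 2, flip, "*")
  scores <- xs %*% load
  rownames(load) <- colnames(m)
  rownames(scores) <- rownames(m)
  disc <- if (length(lambda) > K) lambda[seq(K + 1L, length(lambda))] else numeric()
  new("LatentModel", scaling = scaling, loadings = load,
      component_variances = lambda[seq_len(K)],
      total_variance = sum(lambda), K = as.integer(K),
      training_scores = scores,
      t2_limit = t2Limit(K, n, confidence),
      q_limit = qLimit(disc, confidence),
      confidence = confidence, n_train = as.integer(n))
}

#' Fit a principal-component model with T2/Q critical limits
#'
#' Fits a mean-centered PCA by singular value decomposition (any Pareto
#' scaling or autoscaling is applied beforehand with [applyScaling()], or
#' supplied via `scaling`). Component variances are the eigenvalues of the
#' sample covariance (n-1 denominator). The Hotelling T-squared limit uses
#' the F-distribution form `K(n-1)(n+1)/(n(n-K)) * F(conf; K, n-K)`; the
#' Q-residual limit uses the Jackson-Mudholkar approximation from the
#' discarded eigenvalues.
#'
#' @param table a [PeakTable-class] (already scaled, or raw for a
#'   mean-centered model).
#' @param K number of components, `1 <= K <= min(n_runs - 1, n_features)`
#'   and at most the numerical rank.
#' @param confidence confidence level for both limits (default 0.95).
#' @param scaling optional pre-fitted [ScalingState-class]; by default a
#'   centering state is fitted on `table`.
#' @return a [LatentModel-class].
#' @export
fitPCA <- function(table, K, confidence = 0.95, scaling = NULL) {
  m <- intensities(table)
  if (is.null(scaling)) scaling <- fitScaling(table, "center")
  fitPCAMatrix(m, K, confidence, scaling)
}

#' Explained-variance fractions of a fitted model
#'
#' @param model a [LatentModel-class].
#' @return numeric vector of per-component fractions of total variance.
#' @export
explainedVariance <- function(model) {
  model@component_variances / model@total_variance
}

# internal: project a plain matrix
projectMatrix <- function(model, m) {
  xs <- scaleMatrix(m, model@scaling)
  scores <- xs %*% model@loadings
  t2 <- rowSums(sweep(scores^2, 2, model@component_variances, "/"))
  resid <- xs - scores %*% t(model@loadings)
  q <- rowSums(resid^2)
  rq <- if (model@q_limit > 0) q / model@q_limit else ifelse(q <= 1e-8, 0, Inf)
  list(scores = scores,
       diagnostics = data.frame(
         run_id = rownames(m), t2 = t2, q = q,
         reduced_t2 = t2 / model@t2_limit, reduced_q = rq,
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Project runs into a fitted PCA model
#'
#' Applies the model's scaling, computes scores, Hotelling T-squared
#' (sum of squared scores over component variances), the Q residual
#' (squared reconstruction-residual norm) and their reduced forms
#' (divided by the model's critical limits).
#'
#' @param model a [LatentModel-class].
#' @param table a [PeakTable-class] with exactly the model's features.
#' @return list with `scores` (runs x K) and `diagnostics` (data.frame
#'   with `t2`, `q`, `reduced_t2`, `reduced_q` per run).
#' @export
projectRuns <- function(model, table) {
  m <- intensities(table)
  if (!identical(colnames(m), model@scaling@feature_ids))
    stop("feature set differs from the model's")
  projectMatrix(model, m)
}

# internal: venetian-blinds fold ids along the given order
venetianFolds <- function(n, folds, ord = seq_len(n)) {
  f <- integer(n)
  f[ord] <- (seq_len(n) - 1L) %% folds + 1L
  f
}

#' Cross-validated residual error versus number of components
#'
#' Venetian-blinds cross-validation of a PCA: runs are ordered by
#' (batch, injection order) and run i goes to fold `i mod folds`. The
#' table's feature means (full table) define the centering; each fold's
#' loadings are fitted on the remaining runs and the held-out runs are
#' projected, accumulating the predicted residual sum of squares (naive
#' row-wise PRESS). `K = 0` rows report the total centered sum of
#' squares.
#'
#' @param table a [PeakTable-class] (scaled as desired).
#' @param K_max largest model order to evaluate.
#' @param folds number of folds (default 10; `folds = n` gives
#'   leave-one-out).
#' @return data.frame with columns `K` (0..K_max) and `press`.
#' @export
cvExplainedVariance <- function(table, K_max, folds = 10) {
  m <- intensities(table)
  n <- nrow(m)
  if (folds > n) stop("folds exceeds the number of runs")
  ri <- runInfo(table)
  ord <- order(ri$batch, ri$injection_order)
  fold <- venetianFolds(n, folds, ord)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  press <- numeric(K_max + 1L)
  press[1] <- sum(xc^2)
  for (f in seq_len(folds)) {
    held <- fold == f
    sv <- svd(xc[!held, , drop = FALSE], nu = 0, nv = min(K_max, sum(!held) - 1L, ncol(xc)))
    V <- sv$v
    xh <- xc[held, , drop = FALSE]
    for (K in seq_len(K_max)) {
      Vk <- V[, seq_len(min(K, ncol(V))), drop = FALSE]
      press[K + 1L] <- press[K + 1L] + sum((xh - xh %*% Vk %*% t(Vk))^2)
    }
  }
  data.frame(K = 0:K_max, press = press)
}

#' Screen technical replicates for outliers and average them
#'
#' Operationalizes the replicate-reproducibility check: a mean-centered
#' two-component PCA is fitted on all study runs; a replicate is flagged
#' only when it leaves the T-squared/Q acceptance region at `confidence`
#' (either limit exceeded) and its score-space distance to its sample's
#' replicate centroid exceeds `centroid_mult` times the median
#' within-sample replicate distance. The second condition is what makes
#' the rule a *replicate* screen: a sample whose replicates agree is
#' never flagged however extreme its profile. Unflagged replicates are averaged into one run per
#' sample; samples left with fewer than two replicates are excluded (with
#' a warning), not errors.
#'
#' @param table a [PeakTable-class]; every study sample needs >= 2
#'   replicates.
#' @param confidence acceptance-limit confidence (default 0.95).
#' @param centroid_mult multiplier on the median within-sample distance
#'   (default 3).
#' @return list with `flags` (per study run), `table` (averaged, one run
#'   per retained sample, study runs only) and `excluded` (sample ids).
#' @export
screenReplicates <- function(table, confidence = 0.95, centroid_mult = 3) {
  ri <- runInfo(table)
  st <- which(ri$role == "study")
  if (!length(st)) stop("no study runs to screen")
  reps <- table(ri$sample_id[st])
  if (any(reps < 2)) stop("every sample needs at least 2 replicates")
  sub <- table[, st]
  m <- intensities(sub)
  model <- fitPCAMatrix(m, 2L, confidence,
                        new("ScalingState", method = "center",
                            center = colMeans(m), scale = rep(1, ncol(m)),
                            log10_applied = FALSE, epsilon = NA_real_,
                            feature_ids = colnames(m)))
  pr <- projectMatrix(model, m)
  sc <- pr$scores
  sid <- ri$sample_id[st]
  cent <- rowsum(sc, sid) / as.vector(table(sid))   # both in sorted sid order
  cent <- cent[sid, , drop = FALSE]
  d <- sqrt(rowSums((sc - cent)^2))
  med <- median(d)
  outside <- pr$diagnostics$reduced_t2 > 1 | pr$diagnostics$reduced_q > 1
  flag <- outside & d > centroid_mult * med

  keep_rows <- !flag
  counts <- rowsum(as.numeric(keep_rows), sid)[, 1]
  excluded <- names(counts)[counts < 2]
  if (length(excluded))
    warning("sample(s) excluded after replicate screening: ",
            paste(excluded, collapse = ", "))
  retained <- setdiff(unique(sid), excluded)   # appearance order
  avg <- rowsum(m[keep_rows, , drop = FALSE], sid[keep_rows])
  avg <- avg / counts[rownames(avg)]
  avg <- avg[retained, , drop = FALSE]

  first <- ri[st, ][match(rownames(avg), sid), ]
  run_meta <- data.frame(run_id = rownames(avg), sample_id = rownames(avg),
                         replicate_index = 1L, batch = first$batch,
                         injection_order = first$injection_order,
                         role = "study", group = first$group,
                         stringsAsFactors = FALSE)
  out <- PeakTable(avg, run_meta, featureInfo(table),
                   provenance = c(provenance(table), "replicate_average"))
  list(flags = data.frame(run_id = ri$run_id[st], sample_id = sid,
                          flagged = flag, stringsAsFactors = FALSE),
       table = out, excluded = excluded)
}
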