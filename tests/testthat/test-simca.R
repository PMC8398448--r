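test_that("discriminant power is calibrated near 1 under exchangeability", {
  d <- makeClassTables(100, 100, 80, seed = 31)
  dp <- discriminantPower(d$cls, d$oth, K = 3)
  expect_true(all(dp >= 0))
  expect_lt(abs(median(dp) - 1), 0.2)
})

test_that("a displaced feature earns a top-rank dp and undisplaced features stay low", {
  d <- makeClassTables(60, 60, 200, seed = 37,
                       displace = list(`17` = 10))   # 10 in-class SDs
  dp <- discriminantPower(d$cls, d$oth, K = 3)
  expect_lte(rank(-dp)["F017"], ceiling(0.01 * 200))
  expect_gt(dp["F017"], 1.5)
  # an exchangeable, structure-orthogonal feature sits below the 1.5 cut
  expect_lt(dp["F100"], 1.5)
})

test_that("variable selection is a strict-threshold filter, monotone in the cut", {
  set.seed(41)
  dp <- setNames(rexp(50), sprintf("F%03d", 1:50))
  expect_identical(selectVariables(dp, 0), names(dp)[dp > 0])
  expect_length(selectVariables(dp, max(dp) + 1), 0L)
  got <- selectVariables(dp, 0.7)
  expect_identical(got, names(dp)[dp > 0.7])        # brute force
  for (th in c(0.1, 0.5, 1, 2))
    expect_true(all(selectVariables(dp, th + 0.3) %in%
                    selectVariables(dp, th)))
})

test_that("fitSIMCA honours a forced model order and errors on empty selection", {
  d <- makeClassTables(20, 20, 40, seed = 43,
                       displace = list(`5` = 6, `11` = 6))
  m1 <- fitSIMCA(d$cls, d$oth, K_candidates = 1, dp_threshold = 1.2,
                 method = "center", dpK = 2)
  expect_equal(m1@K, 1L)
  expect_true(all(m1@dp[m1@selected_features] > 1.2))
  expect_error(fitSIMCA(d$cls, d$oth, K_candidates = 1, dp_threshold = 1e6,
                        method = "center", dpK = 2), "threshold")
  expect_error(fitSIMCA(d$cls[, 1:4], d$oth, K_candidates = 1:6),
               "at least")
})

test_that("decisions follow the sqrt(2) combined-distance rule, boundary inclusive", {
  d <- makeClassTables(25, 10, 30, seed = 47, displace = list(`3` = 8))
  model <- fitSIMCA(d$cls, d$oth, K_candidates = 1:3, dp_threshold = 1.2,
                    method = "center", dpK = 2)
  dec <- classifyRuns(model, d$cls)
  # class centroid projects to distance ~0 and is accepted
  centroid <- PeakTable(rbind(colMeans(intensities(d$cls))),
                        toyRunInfo(1), toyFeatureInfo(30))
  cdec <- classifyRuns(model, centroid)
  expect_lt(cdec$distance, 1e-6)
  expect_true(cdec$accepted)
  # boundary semantics on the invariant itself
  expect_identical(dec$accepted, dec$distance <= sqrt(2))
  expect_true(all(abs(dec$distance -
                      sqrt(dec$reduced_t2^2 + dec$reduced_q^2)) < 1e-12))

  # compositional oracle: recompute decisions from projectRuns()
  sub <- dropFeatures(d$oth, setdiff(rownames(d$oth),
                                     model@selected_features))
  pr <- projectRuns(model@inner,
                    PeakTable(intensities(sub)[, model@selected_features],
                              runInfo(d$oth),
                              featureInfo(sub)[match(model@selected_features,
                                                     featureInfo(sub)$feature_id), ]))
  want <- sqrt(pr$diagnostics$reduced_t2^2 + pr$diagnostics$reduced_q^2)
  got <- classifyRuns(model, d$oth)
  expect_equal(got$distance, want, tolerance = 1e-12)
  expect_identical(got$accepted, want <= model@distance_limit)

  expect_error(classifyRuns(model, dropFeatures(d$oth, "F003")), "lacks")
})

test_that("confusion summaries reproduce printed-count arithmetic with half-up rounding", {
  cs <- confusionSummary(tp = 23, fn = 1, tn = 42, fp = 15)
  expect_equal(percentHalfUp(sensitivity(cs)), 96L)   # 95.83 -> 96
  expect_equal(percentHalfUp(specificity(cs)), 74L)   # 73.68 -> 74
  all_in <- confusionSummary(tp = 24, fn = 0, tn = 0, fp = 57)
  expect_equal(percentHalfUp(sensitivity(all_in)), 100L)
  expect_equal(percentHalfUp(specificity(all_in)), 0L)
  expect_error(confusionSummary(-1, 0, 0, 0))
})

test_that("serial fusion is an AND rule whose false positives are the set intersection", {
  ids <- sprintf("S%02d", 1:57)
  set.seed(53)
  fp_rp <- sample(ids, 15)
  fp_hl <- c(sample(fp_rp, 4), sample(setdiff(ids, fp_rp), 10))
  dec <- function(acc) data.frame(sample_id = ids, reduced_t2 = 0,
                                  reduced_q = 0, distance = 0,
                                  accepted = ids %in% acc,
                                  stringsAsFactors = FALSE)
  fused <- serialFusion(dec(fp_rp), dec(fp_hl))
  expect_setequal(fused$sample_id[fused$accepted], intersect(fp_rp, fp_hl))
  expect_equal(sum(fused$accepted), 4L)
  expect_equal(percentHalfUp(sum(fused$accepted) / 57), 7L)   # 4/57 -> 7%
  # RP-negative samples can never be fused-positive
  expect_true(all(!fused$accepted[!fused$accepted_rp]))
  expect_error(serialFusion(dec(fp_rp)[-1, ], dec(fp_hl)), "same sample")
})

test_that("fusion dominance: fused false-positive count never exceeds either mode", {
  set.seed(59)
  ids <- sprintf("S%02d", 1:40)
  for (i in 1:20) {
    a <- sample(ids, sample(0:40, 1))
    b <- sample(ids, sample(0:40, 1))
    dec <- function(acc) data.frame(sample_id = ids, accepted = ids %in% acc)
    fused <- serialFusion(dec(a), dec(b))
    expect_lte(sum(fused$accepted), min(length(a), length(b)))
  }
})

test_that("raising the acceptance limit trades specificity for sensitivity monotonically", {
  d <- makeClassTables(24, 30, 60, seed = 61, displace = list(`7` = 4, `21` = 4))
  model <- fitSIMCA(d$cls, d$oth, K_candidates = 1:3, dp_threshold = 1.2,
                    method = "center", dpK = 2)
  sens <- spec <- numeric(0)
  for (lim in c(0.5, 1, sqrt(2), 2, 4)) {
    m2 <- model; m2@distance_limit <- lim
    cd <- classifyRuns(m2, d$cls); od <- classifyRuns(m2, d$oth)
    sens <- c(sens, mean(cd$accepted)); spec <- c(spec, mean(!od$accepted))
  }
  expect_true(all(diff(sens) >= 0))
  expect_true(all(diff(spec) <= 0))
})

test_that("on separable synthetic data the chosen model accepts held-out class runs", {
  cfg <- syntheticConfig(fentanyl_effect = 2, seed = 67)
  out <- generateUrineStudy(cfg, modes = "RP")
  tab <- normalizeInternalStandard(filterSparse(out$rp, 0.15,
                                                keep = "RP_IS_fentanylD5"),
                                   "RP_IS_fentanylD5")
  tab <- suppressWarnings(screenReplicates(tab))$table
  tab <- dropFeatures(tab, intersect(
    c(unlist(out$truth$rp$drug_feature_ids), "RP_IS_fentanylD5"),
    rownames(tab)))
  ri <- runInfo(tab)
  cls <- tab[, ri$group == "fentanyl"]
  oth <- tab[, ri$group != "fentanyl"]
  cv <- crossValidatedDecisions(cls, oth, K_candidates = 1:6,
                                dp_threshold = 1.5, method = "pareto")
  expect_gte(sensitivity(cv$confusion), 0.90)
  expect_lte(cv$model@K, 6L)
  expect_true(all(cv$model@rmsecv_curve$rmsecv >= 0))
})
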