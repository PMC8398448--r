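test_that("sparsity filter uses an inclusive >= threshold and matches brute-force counting", {
  set.seed(5)
  m <- matrix(exp(rnorm(100 * 3, 8, 1)), 100, 3)
  m[15:100, 1] <- 0      # detected in 14/100
  m[16:100, 2] <- 0      # detected in 15/100
  tab <- PeakTable(m, toyRunInfo(100), toyFeatureInfo(3))
  kept <- rownames(filterSparse(tab, 0.15))
  expect_false("F001" %in% kept)
  expect_true(all(c("F002", "F003") %in% kept))

  dense <- randomTable(10, 20, seed = 6)
  expect_identical(intensities(filterSparse(dense, 0.15)),
                   intensities(dense))

  zi <- randomTable(40, 200, seed = 7, zeros = 0.5)
  got <- nFeatures(filterSparse(zi, 0.3))
  want <- sum(colMeans(intensities(zi) > 0) >= 0.3)   # brute force
  expect_equal(got, want)
})

test_that("blank runs are excluded from the sparsity denominator", {
  m <- rbind(matrix(5, 8, 2), matrix(0, 2, 2))   # blanks all-zero
  m[1:7, 1] <- 0                                 # 1/8 nonzero among non-blanks
  ri <- toyRunInfo(10, roles = c(rep("study", 8), rep("blank", 2)))
  tab <- PeakTable(m, ri, toyFeatureInfo(2))
  kept <- rownames(filterSparse(tab, 0.15))
  expect_identical(kept, "F002")                 # 1/8 = 12.5% < 15%
})

test_that("total-area normalization gives unit row sums and is idempotent", {
  m <- rbind(c(2, 3, 5), c(1, 1, 2))
  tab <- PeakTable(m, toyRunInfo(2), toyFeatureInfo(3))
  n1 <- normalizeTotalArea(tab)
  expect_equal(unname(intensities(n1)[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(intensities(n1))), c(1, 1))
  n2 <- normalizeTotalArea(n1)
  expect_equal(intensities(n2), intensities(n1), tolerance = 1e-15)

  big <- randomTable(30, 50, seed = 8)
  expect_lt(max(abs(rowSums(intensities(normalizeTotalArea(big))) - 1)), 1e-12)

  zr <- PeakTable(rbind(c(1, 2), c(0, 0)), toyRunInfo(2), toyFeatureInfo(2))
  expect_error(normalizeTotalArea(zr), "R02")
})

isTable <- function(batch_scale = c(1, 1), qc_area = c(10, 10, 10, 10)) {
  # 2 batches, 2 QCs + 2 study runs each; feature F003 is the standard
  n <- 8
  roles <- rep(c("qc", "study", "qc", "study"), 2)
  batches <- rep(0:1, each = 4)
  ri <- toyRunInfo(n, roles = roles, batches = batches)
  m <- matrix(rep(c(0, 100), 12), n, 3)
  m[, 3] <- 0
  m[roles == "qc", 3] <- qc_area
  m <- m * rep(batch_scale[batches + 1], 3)
  PeakTable(m, ri, toyFeatureInfo(3))
}

test_that("internal-standard normalization: unit factors leave the table unchanged", {
  tab <- isTable()
  out <- normalizeInternalStandard(tab, "F003")
  expect_equal(intensities(out), intensities(tab), tolerance = 1e-14)
})

test_that("internal-standard normalization inverts a batch-level scale change", {
  base <- isTable()
  scaled <- isTable(batch_scale = c(1, 3))   # batch 1 inflated x3 incl. QCs
  out <- normalizeInternalStandard(scaled, "F003")
  ri <- runInfo(base)
  st <- ri$role == "study"
  # relative level of batch 1 vs batch 0 is restored
  rel_before <- intensities(scaled)[st & ri$batch == 1, 1] /
    intensities(scaled)[st & ri$batch == 0, 1]
  rel_after <- intensities(out)[st & ri$batch == 1, 1] /
    intensities(out)[st & ri$batch == 0, 1]
  expect_equal(unname(rel_before), c(3, 3))
  expect_equal(unname(rel_after), c(1, 1), tolerance = 1e-12)
  # matches the per-QC ratio definition exactly
  qc <- ri$role == "qc"
  f <- intensities(scaled)[, "F003"] / mean(intensities(scaled)[qc, "F003"])
  expect_equal(unname(intensities(out)[2, 1]),
               unname(intensities(scaled)[2, 1] / f[1]))  # anchored to QC run 1
  expect_error(normalizeInternalStandard(isTable(qc_area = c(0, 1, 1, 1)),
                                         "F003"), "zero internal-standard")
})

test_that("internal-standard normalization removes between-batch QC variance on synthetic data", {
  cfg <- syntheticConfig(n_features = 300, batch_sd = 0.5, seed = 21)
  out <- generateUrineStudy(cfg, modes = "RP")
  tab <- out$rp
  ri <- runInfo(tab)
  qc <- ri$role == "qc"
  pre <- tapply(intensities(tab)[qc, "RP_IS_fentanylD5"], ri$batch[qc], mean)
  corr <- normalizeInternalStandard(tab, "RP_IS_fentanylD5")
  post <- tapply(intensities(corr)[qc, "RP_IS_fentanylD5"], ri$batch[qc], mean)
  expect_lt(var(post), 0.01 * var(pre))
})

test_that("pool-profile normalization matches its defining brute-force recomputation", {
  set.seed(30)
  n <- 12
  roles <- rep(c("pool", "study", "study"), 4)
  batches <- rep(0:1, each = 6)
  ri <- toyRunInfo(n, roles = roles, batches = batches)
  m <- matrix(exp(rnorm(n * 5, 6, 0.5)), n, 5) *
    rep(c(1, 1, 1, 1, 1, 1, 3, 3, 3, 3, 3, 3))   # batch 1 scaled x3
  tab <- PeakTable(m, ri, toyFeatureInfo(5))
  out <- normalizePoolProfile(tab)

  prof <- rowMeans(m)
  f <- prof / mean(prof[roles == "pool"])
  anchor <- integer(n)
  for (i in seq_len(n)) {
    inb <- which(batches == batches[i] & roles == "pool" &
                 ri$injection_order <= ri$injection_order[i])
    anchor[i] <- inb[which.max(ri$injection_order[inb])]
  }
  expect_equal(unname(intensities(out)), m / f[anchor], tolerance = 1e-14)

  ident <- PeakTable(matrix(4, 4, 2),
                     toyRunInfo(4, roles = c("pool", "study", "pool", "study")),
                     toyFeatureInfo(2))
  expect_equal(intensities(normalizePoolProfile(ident)), intensities(ident))
  expect_error(normalizePoolProfile(randomTable(3, 2)), "no pool runs")
})

test_that("batch normalizations are invariant to batch relabeling", {
  cfg <- syntheticConfig(n_features = 150, seed = 33)
  tab <- generateUrineStudy(cfg, modes = "RP")$rp
  out1 <- intensities(normalizeInternalStandard(tab, "RP_IS_fentanylD5"))
  relab <- tab
  SummarizedExperiment::colData(relab)$batch <-
    9L - SummarizedExperiment::colData(relab)$batch   # 0,1,2 -> 9,8,7
  out2 <- intensities(normalizeInternalStandard(relab, "RP_IS_fentanylD5"))
  expect_equal(out1, out2, tolerance = 1e-14)
})

test_that("log10 transform is monotone and invertible away from the offset", {
  tab <- randomTable(6, 25, seed = 44, zeros = 0.2)
  m <- intensities(tab)
  lt <- log10Transform(tab)
  eps <- min(m[m > 0])
  lm <- intensities(lt)
  # strictly increasing in x
  o <- order(m[1, ]); expect_true(all(diff(lm[1, o][!duplicated(m[1, o])]) > 0))
  back <- 10^lm - eps
  big <- m > 10 * eps
  expect_gt(sum(big), 0)
  expect_lt(max(abs(back[big] - m[big]) / m[big]), 1e-9)
  zero <- PeakTable(matrix(0, 2, 2), toyRunInfo(2), toyFeatureInfo(2))
  expect_error(log10Transform(zero), "all-zero")
})

test_that("scaling methods have their defining column moments", {
  tab <- randomTable(15, 10, seed = 55)
  a <- intensities(applyScaling(tab, fitScaling(tab, "autoscale")))
  expect_lt(max(abs(colMeans(a))), 1e-10)
  expect_lt(max(abs(apply(a, 2, var) - 1)), 1e-10)

  p <- intensities(applyScaling(tab, fitScaling(tab, "pareto")))
  sds <- apply(intensities(tab), 2, sd)
  expect_lt(max(abs(apply(p, 2, var) - sds)), 1e-8)

  cc <- intensities(tab); cc[, 3] <- 7
  ctab <- PeakTable(cc, runInfo(tab), toyFeatureInfo(10))
  for (meth in c("center", "pareto", "autoscale")) {
    s <- intensities(applyScaling(ctab, fitScaling(ctab, meth)))
    expect_true(all(s[, 3] == 0))
  }
})

test_that("fitted scaling inverts to the original table", {
  tab <- randomTable(12, 8, seed = 66)
  st <- fitScaling(tab, "autoscale")
  sc <- intensities(applyScaling(tab, st))
  back <- sweep(sweep(sc, 2, st@scale, "*"), 2, st@center, "+")
  expect_lt(max(abs(back - intensities(tab)) / intensities(tab)), 1e-9)
  expect_error(applyScaling(randomTable(12, 9, seed = 1), st), "feature set")
})

test_that("control-mean subtraction zeroes the control mean and matches brute force", {
  tab <- randomTable(10, 6, seed = 77)
  ctrl <- sprintf("S%02d", 1:4)
  out <- subtractControlMean(tab, ctrl)
  m <- intensities(out)
  ri <- runInfo(tab)
  expect_lt(max(abs(colMeans(m[ri$sample_id %in% ctrl, ]))), 1e-10)
  mu <- colMeans(intensities(tab)[ri$sample_id %in% ctrl, ])
  expect_equal(m, sweep(intensities(tab), 2, mu), tolerance = 1e-14)
  expect_error(subtractControlMean(tab, "nope"), "unknown")
})

test_that("dropFeatures slices exactly and commutes with the sparsity filter", {
  tab <- randomTable(20, 30, seed = 88, zeros = 0.4)
  expect_identical(intensities(dropFeatures(tab, character())),
                   intensities(tab))
  all_gone <- dropFeatures(tab, rownames(tab))
  expect_equal(nFeatures(all_gone), 0L)

  drop <- rownames(tab)[c(2, 9, 25)]
  a <- filterSparse(dropFeatures(tab, drop), 0.3)
  b <- dropFeatures(filterSparse(tab, 0.3),
                    intersect(drop, rownames(filterSparse(tab, 0.3))))
  expect_identical(rownames(a), rownames(b))
  expect_identical(intensities(a), intensities(b))
})

test_that("provenance records every transformation in order", {
  tab <- randomTable(10, 12, seed = 99, zeros = 0.2)
  out <- applyScaling(
    log10Transform(normalizeTotalArea(filterSparse(tab, 0.1))),
    fitScaling(log10Transform(normalizeTotalArea(filterSparse(tab, 0.1))),
               "pareto"))
  pv <- provenance(out)
  expect_match(pv[1], "^filter_sparse")
  expect_match(pv[2], "^normalize_total_area")
  expect_match(pv[3], "^log10")
  expect_match(pv[4], "^scale:pareto")
})
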