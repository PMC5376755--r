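test_that("well-separated blobs are recovered perfectly", {
  set.seed(1)
  m <- cbind(matrix(rnorm(50 * 6, 10, 0.3), 50), # 6 high-expressing
             matrix(rnorm(50 * 9, 5, 0.3), 50))  # 9 low-expressing
  dimnames(m) <- list(paste0("T", 1:50), paste0("s", 1:15))
  cl <- clusterMycActivity(m, rownames(m))
  expect_identical(as.character(cl$labels),
                   rep(c("high", "low"), c(6, 9)))
})

test_that("2-cut matches the exhaustive complete-linkage oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:6, 1)
    m <- matrix(rnorm(8 * n, 7), 8, n,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:n)))
    cl <- clusterMycActivity(m, rownames(m))
    oracle <- oracleCompleteLinkage2(dist(t(m)))
    expect_equal(partitionAgreement(cl$labels, oracle), 1)
  }
})

test_that("default synthetic cohort clusters into the 17/38 split", {
  ch <- simulateCohort(cohortConfig(seed = 1))
  cl <- clusterMycActivity(ch, mycTargetGenes())
  expect_equal(sum(cl$labels == "high"), 17)
  expect_identical(as.character(cl$labels), as.character(trueLabels(ch)))
})

test_that("clustering is invariant to sample and gene order", {
  ch <- simulateCohort(cohortConfig(n_patients = 30, seed = 3))
  m <- log2(SummarizedExperiment::assay(ch))
  targets <- mycTargetGenes()
  base <- clusterMycActivity(m, targets)
  set.seed(4)
  perm <- sample(ncol(m))
  shuffled <- clusterMycActivity(m[sample(nrow(m)), perm], targets)
  expect_identical(shuffled$labels[colnames(m)], base$labels)
})

test_that("clustering contracts: degenerate inputs rejected, unresolved listed", {
  m <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_error(clusterMycActivity(m, rownames(m)), "identical")
  expect_error(clusterMycActivity(m[, 1:2], rownames(m)), "3 samples")
  set.seed(1); m2 <- m + matrix(rnorm(20), 5)
  cl <- clusterMycActivity(m2, c(rownames(m2), "NOT_THERE"))
  expect_identical(cl$unresolved, "NOT_THERE")
})

test_that("matrix Welch t agrees with stats::t.test per gene", {
  # single-gene textbook case
  x <- matrix(log2(c(1, 2, 3, 4, 5, 6)), 1,
              dimnames = list("g", paste0("s", 1:6)))
  # on raw values {1,2,3} vs {4,5,6}
  xr <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = dimnames(x))
  labels <- rep(c("high", "low"), each = 3)
  tab <- rankGenes(xr, labels)
  expect_equal(tab$t, oracleWelchT(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(tab$p, t.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  # random matrix, every gene
  set.seed(5)
  m <- matrix(rnorm(30 * 11), 30, dimnames = list(paste0("g", 1:30), NULL))
  lab <- rep(c("high", "low"), c(5, 6))
  tab2 <- rankGenes(m, lab)
  for (g in sample(rownames(m), 6)) {
    ht <- t.test(m[g, lab == "high"], m[g, lab == "low"])
    row <- tab2[tab2$gene == g, ]
    expect_equal(row$t, unname(ht$statistic), tolerance = 1e-12)
    expect_equal(row$p, ht$p.value, tolerance = 1e-12)
  }
  expect_false(is.unsorted(rev(tab2$t)))  # sorted by t descending
})

test_that("degenerate zero-variance genes are flagged and ranked last", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = rep(2, 6))
  colnames(m) <- paste0("s", 1:6)
  tab <- rankGenes(m, rep(c("high", "low"), each = 3))
  expect_true(tab$degenerate[tab$gene == "g2"])
  expect_equal(tab$gene[nrow(tab)], "g2")
})

test_that("t-test p-values are uniform under label permutation", {
  ch <- simulateCohort(cohortConfig(n_patients = 40, seed = 8))
  m <- log2(SummarizedExperiment::assay(ch))
  set.seed(9)
  permuted <- sample(as.character(trueLabels(ch)))
  p <- rankGenes(m, permuted)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH q-values match the step-up closed form", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("marker selection recovers the planted panel at default effect", {
  ch <- simulateCohort(cohortConfig(seed = 1))
  cl <- clusterMycActivity(ch, mycTargetGenes())
  ranked <- rankGenes(ch, cl$labels)
  pan <- selectMarkerPanel(ranked, mycTargetGenes())
  expect_setequal(upGenes(pan), upGenes(mycMarkerPanel()))
  expect_setequal(downGenes(pan), downGenes(mycMarkerPanel()))
  expect_length(c(upGenes(pan), downGenes(pan)), 16)
  # up-markers sit at the top of the positive tail among target genes
  targetTab <- ranked[ranked$gene %in% mycTargetGenes(), ]
  expect_setequal(targetTab$gene[1:10], upGenes(mycMarkerPanel()))
  expect_error(selectMarkerPanel(ranked, mycTargetGenes(), nUp = 1e4),
               "up-candidate")
})

test_that("null input still returns a full panel (unstable but sized)", {
  ch <- simulateCohort(cohortConfig(n_patients = 30, panel_log2fc = 0,
                                    seed = 12))
  ranked <- rankGenes(ch, trueLabels(ch))
  pan <- selectMarkerPanel(ranked, mycTargetGenes())
  expect_length(c(upGenes(pan), downGenes(pan)), 16)
})

test_that("cluster recovery of planted labels is strong across seeds", {
  ari <- vapply(1:20, function(s) {
    ch <- simulateCohort(cohortConfig(seed = s))
    cl <- clusterMycActivity(ch, mycTargetGenes())
    adjustedRand(cl$labels, trueLabels(ch))
  }, numeric(1))
  expect_true(all(ari >= 0.9))
})

test_that("wilcoxon rank metric is available and sensible", {
  ch <- simulateCohort(cohortConfig(n_patients = 30, seed = 14))
  tab <- rankGenes(ch, trueLabels(ch), method = "wilcoxon")
  up <- upGenes(mycMarkerPanel())
  expect_true(all(tab$gene[1:10] %in% mycTargetGenes()))
  expect_gt(countIncreased(tab, mycTargetGenes()), 100)
})
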