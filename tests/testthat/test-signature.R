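test_that("the default marker panel has 10 up and 6 down genes, disjoint", {
  panel <- mycMarkerPanel()
  expect_length(upGenes(panel), 10)
  expect_length(downGenes(panel), 6)
  expect_length(intersect(upGenes(panel), downGenes(panel)), 0)
  expect_error(MarkerPanel(up = c("A", "B"), down = "A"), "both lists")
  expect_error(MarkerPanel(up = character(0), down = "A"))
})

test_that("mean-centered normalization conserves row totals of 100", {
  m <- matrix(c(2, 3, 5), 1, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(as.numeric(meanCenterNormalize(m)), c(20, 30, 50))
  # single sample: everything is 100
  one <- matrix(c(4, 9), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_true(all(meanCenterNormalize(one) == 100))
  # conservation on a random matrix
  set.seed(1)
  r <- matrix(rexp(60), 6, 10, dimnames = list(letters[1:6], NULL))
  expect_equal(unname(rowSums(meanCenterNormalize(r))), rep(100, 6))
  # rescaling one marker's raw row leaves its normalized row unchanged
  r2 <- r; r2[3, ] <- r2[3, ] * 37.5
  expect_equal(meanCenterNormalize(r2)[3, ], meanCenterNormalize(r)[3, ])
  # zero-total marker is a named error
  rz <- r; rz["c", ] <- 0
  expect_error(meanCenterNormalize(rz), "c")
})

test_that("ratio construction yields K*L ratios with the worked toy values", {
  # K = L = 2 toy: U = (20, 30), D = (10, 40) per sample
  U <- matrix(c(20, 30), 2, 1, dimnames = list(c("u1", "u2"), "s"))
  D <- matrix(c(10, 40), 2, 1, dimnames = list(c("d1", "d2"), "s"))
  r <- signatureRatios(U, D)
  expect_setequal(as.numeric(r), c(2.0, 3.0, 0.5, 0.75))
  expect_equal(nrow(r), 4)
  # all-equal normalized values give all-1 ratios
  E <- matrix(25, 2, 1, dimnames = list(c("x", "y"), "s"))
  expect_true(all(signatureRatios(E, E[1, , drop = FALSE]) == 1))
  # down-marker dropout is an error
  D0 <- D; D0[1, 1] <- 0
  expect_error(signatureRatios(U, D0), "dropout")
  expect_error(signatureRatios(U, matrix(1, 2, 2)), "same samples")
})

test_that("median-threshold classification follows the strict rule", {
  c1 <- classifyRatios(c(2.0, 0.5, 3.0, 0.75))
  expect_equal(c1$score, 1.375)
  expect_equal(c1$label, "MYC-high")
  expect_false(c1$boundary)
  c2 <- classifyRatios(rep(1, 5))
  expect_equal(c2$score, 1)
  expect_equal(c2$label, "MYC-low")  # strict inequality: 1 is not high
  expect_true(c2$boundary)
  c3 <- classifyRatios(c(0.2, 0.4, 0.9))
  expect_equal(c3$score, 0.4)
  expect_equal(c3$label, "MYC-low")
  expect_error(classifyRatios(numeric(0)), "empty")
  expect_error(classifyRatios(c(1, -2)), "positive")
})

test_that("default panel scoring produces 60 ratios per sample", {
  m <- makeToyCohortMatrix()
  sc <- scoreSignature(m)
  expect_equal(nrow(sigRatios(sc)), 60)
  expect_equal(length(sigScore(sc)), ncol(m))
  expect_identical(as.character(sigLabel(sc)),
                   ifelse(attr(m, "labels") == "high", "MYC-high", "MYC-low"))
})

test_that("per-gene rescaling never changes a call (platform robustness)", {
  m <- makeToyCohortMatrix(seed = 11)
  base <- scoreSignature(m)
  set.seed(2)
  for (g in sample(c(upGenes(mycMarkerPanel()), downGenes(mycMarkerPanel())), 4)) {
    m2 <- m
    m2[g, ] <- m2[g, ] * runif(1, 0.01, 100)
    expect_identical(sigLabel(scoreSignature(m2)), sigLabel(base))
  }
})

test_that("scores are cohort-dependent: adding a sample can move another", {
  m <- makeToyCohortMatrix(seed = 13)
  full <- scoreSignature(m)
  drop1 <- scoreSignature(m[, -1])
  shared <- intersect(names(sigScore(full)), names(sigScore(drop1)))
  expect_false(isTRUE(all.equal(sigScore(full)[shared],
                                sigScore(drop1)[shared])))
})

test_that("swapping up and down roles inverts an odd-sized median exactly", {
  set.seed(3)
  m <- 2^matrix(rnorm(4 * 6, 7), 4, 6,
                dimnames = list(c("u1", "d1", "d2", "d3"), paste0("s", 1:6)))
  pan <- MarkerPanel(up = "u1", down = c("d1", "d2", "d3"))   # K*L = 3, odd
  swapped <- MarkerPanel(up = c("d1", "d2", "d3"), down = "u1")
  expect_equal(sigScore(scoreSignature(m, swapped)),
               1 / sigScore(scoreSignature(m, pan)))
})

test_that("scoring rejects missing markers and nonpositive expression", {
  m <- makeToyCohortMatrix()
  expect_error(scoreSignature(m[-1, ]), "CDC20")
  m2 <- m; m2["CDC20", 1] <- 0
  expect_error(scoreSignature(m2), "strictly positive")
})

test_that("log2-tagged input is exponentiated exactly once before scoring", {
  m <- makeToyCohortMatrix(seed = 21)
  expect_identical(sigScore(scoreSignature(log2(m), scale = "log2")),
                   sigScore(scoreSignature(m, scale = "linear")))
})

test_that("delta-delta-Ct relative quantities match the closed form", {
  expect_equal(ddctQuantity(20, 20, 20, 20), 1)
  expect_equal(ddctQuantity(24, 12, 26, 12), 4)   # ddCt = -2
  expect_equal(ddctQuantity(21, 15, 20, 15), 0.5) # ddCt = +1
  expect_error(ddctQuantity(NA, 1, 1, 1), "finite")
})

test_that("the qPCR scoring path recovers the true labels end to end", {
  cfg <- cohortConfig(n_patients = 24, qpcr_noise_sd = 0.1, seed = 6)
  ch <- simulateCohort(cfg)
  sc <- scoreSignatureQpcr(qpcrData(ch))
  truth <- setNames(ifelse(trueLabels(ch) == "high", "MYC-high", "MYC-low"),
                    colnames(ch))
  expect_identical(as.character(sigLabel(sc)),
                   unname(truth[names(sigScore(sc))]))
  # noiseless, equal expression everywhere: every RQ is 1
  flat <- data.frame(
    sample_id = rep(c("a", "b"), each = 17),
    gene = rep(c(upGenes(mycMarkerPanel()), downGenes(mycMarkerPanel()),
                 "RN28S"), 2),
    ct = rep(c(rep(25, 16), 13), 2))
  scFlat <- scoreSignatureQpcr(flat)
  expect_true(all(sigRatios(scFlat) == 1))
  expect_true(all(boundaryFlag(scFlat)))
})

test_that("signatureTable emits the per-sample report schema", {
  sc <- scoreSignature(makeToyCohortMatrix())
  tab <- signatureTable(sc, ratios = TRUE)
  expect_named(tab[, 1:4], c("sample_id", "score", "label", "boundary_flag"))
  expect_equal(ncol(tab), 4 + 60)
})
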