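test_that("config validation rejects degenerate parameters", {
  expect_error(cohortConfig(n_patients = 1), "at least 2")
  expect_error(cohortConfig(frac_high = 1.2), "frac_high")
  expect_error(cohortConfig(surv_median_high = -1), "surv_median_high")
  expect_error(cohortConfig(ic50_low = 0), "ic50_low")
  expect_error(cohortConfig(n_doses = 2.5), "n_doses")
})

test_that("default cohort reproduces the 17/55 high-prevalence quota", {
  ch <- simulateCohort(cohortConfig(seed = 1))
  expect_equal(sum(trueLabels(ch) == "high"), 17)
  expect_equal(ncol(ch), 55)
  expect_true(all(SummarizedExperiment::assay(ch, "exprs") > 0))
  # quota is exact for any seed
  ch2 <- simulateCohort(cohortConfig(seed = 99))
  expect_equal(sum(trueLabels(ch2) == "high"), 17)
  expect_warning(simulateCohort(cohortConfig(n_patients = 10,
                                             frac_high = 0.01)),
                 "single group")
})

test_that("identical config and seed give a bit-identical cohort", {
  a <- simulateCohort(cohortConfig(n_patients = 20, seed = 7))
  b <- simulateCohort(cohortConfig(n_patients = 20, seed = 7))
  expect_identical(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
  expect_identical(chemograms(a), chemograms(b))
  expect_identical(qpcrData(a), qpcrData(b))
  expect_identical(survivalData(a), survivalData(b))
  c <- simulateCohort(cohortConfig(n_patients = 20, seed = 8))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
})

test_that("zero effect size removes the marker group difference", {
  ch <- simulateCohort(cohortConfig(n_patients = 40, panel_log2fc = 0,
                                    noise_sd = 1e-9, seed = 2))
  m <- log2(SummarizedExperiment::assay(ch))
  panel <- mycMarkerPanel()
  high <- trueLabels(ch) == "high"
  for (g in c(upGenes(panel), downGenes(panel)))
    expect_equal(mean(m[g, high]), mean(m[g, !high]), tolerance = 1e-6)
})

test_that("planted up-marker effect matches the configured log2FC", {
  ch <- simulateCohort(cohortConfig(n_patients = 200, panel_log2fc = 2,
                                    seed = 7))
  m <- log2(SummarizedExperiment::assay(ch))
  high <- trueLabels(ch) == "high"
  up <- upGenes(mycMarkerPanel())
  diffs <- rowMeans(m[up, high]) - rowMeans(m[up, !high])
  # each mean difference within 3 SE of the generating value
  se <- 0.5 * sqrt(1 / sum(high) + 1 / sum(!high))
  expect_true(all(abs(diffs - 2) < 3 * se))
  # down-markers reciprocal
  down <- downGenes(mycMarkerPanel())
  ddiffs <- rowMeans(m[down, high]) - rowMeans(m[down, !high])
  expect_true(all(abs(ddiffs + 2) < 3 * se))
})

test_that("background genes carry no systematic group effect", {
  ch <- simulateCohort(cohortConfig(n_patients = 60, seed = 5))
  m <- log2(SummarizedExperiment::assay(ch))
  bg <- grep("^BG", rownames(m), value = TRUE)
  p <- rankGenes(m[bg, ], trueLabels(ch))$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("survival generator honors medians, censoring and edge cases", {
  expect_error(simulateSurvival(character(0)), "nonempty")
  badCfg <- cohortConfig()
  badCfg$surv_median_high <- -1  # bypass constructor to hit the op's guard
  expect_error(simulateSurvival("high", badCfg), "medians")
  s <- simulateSurvival(rep("low", 1000), cohortConfig(censor_rate = 0),
                        seed = 3)
  expect_true(all(s$time_months > 0))
  expect_true(all(s$event == 1))
  expect_equal(kmEstimate(s$time_months, s$event)$median, 18.8,
               tolerance = 0.1)
  expect_warning(
    sc <- simulateSurvival(rep("high", 30), cohortConfig(censor_rate = 1),
                           seed = 3),
    "all records censored")
  expect_true(all(sc$event == 0))
  expect_true(isTRUE(attr(sc, "all_censored")))
})

test_that("noiseless chemograms hit the 4PL anchor points", {
  cfg <- cohortConfig(viab_noise_sd = 0)
  ch <- simulateChemogram("high", cfg, seed = 1)
  expect_equal(sort(unique(ch$dose_uM))[1], 0)
  expect_length(unique(ch$dose_uM), 10)
  expect_equal(max(ch$dose_uM), 30)
  expect_true(all(ch$viability_pct[ch$dose_uM == 0] == 100))
  # midpoint: viability at d = IC50 is exactly 50
  expect_equal(fourPL(cfg$ic50_high, 0, 100, cfg$hill, cfg$ic50_high), 50)
  low <- simulateChemogram("low", cfg, seed = 1)
  expect_true(mean(low$viability_pct) > mean(ch$viability_pct))
})

test_that("degenerate histology noise collapses scores to the rounded means", {
  cfg0 <- cohortConfig(ki67_sd = 1e-12, diff_sd = 1e-12)
  h <- simulateHistoScores(rep("high", 10), cfg0, seed = 1)
  expect_true(all(h$ki67 == 3))  # nearest integer to 2.88
  l <- simulateHistoScores(rep("low", 10), cfg0, seed = 1)
  expect_true(all(l$diff == 2))  # nearest integer to 1.82
  expect_true(all(l$ki67 == 2))  # nearest integer to 2.06
})

test_that("high group proliferates more than low in large samples", {
  h <- simulateHistoScores(rep(c("high", "low"), each = 500),
                           cohortConfig(), seed = 9)
  cmp <- groupCompare(h$ki67[h$group == "high"], h$ki67[h$group == "low"],
                      "welch")
  expect_gt(mean(h$ki67[h$group == "high"]),
            mean(h$ki67[h$group == "low"]))
  expect_lt(cmp$p, 0.05)
  expect_true(all(h$ki67 %in% 0:4))
  expect_true(all(h$diff %in% 0:2))
})

test_that("qPCR Ct table encodes the expression fold structure", {
  cfg <- cohortConfig(n_patients = 10, qpcr_noise_sd = 0, noise_sd = 0.3,
                      seed = 4)
  ch <- simulateCohort(cfg)
  qp <- qpcrData(ch)
  expect_setequal(unique(qp$gene),
                  c(upGenes(mycMarkerPanel()), downGenes(mycMarkerPanel()),
                    "RN28S"))
  # noiseless Ct difference between two samples equals -delta log2 expression
  m <- log2(SummarizedExperiment::assay(ch))
  ctc <- qp[qp$gene == "CDC20", ]
  expect_equal(ctc$ct[1] - ctc$ct[2],
               -(m["CDC20", ctc$sample_id[1]] - m["CDC20", ctc$sample_id[2]]),
               tolerance = 1e-9)
})
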