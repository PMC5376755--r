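#' Configuration for a synthetic PDX expression cohort
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' reproduce the statistical structure of the published 55-PDX pancreatic
#' cancer study cohort: a 17/55 MYC-high prevalence, a 239-gene MYC-target
#' expression block elevated in the high group, six reciprocal down-markers,
#' exponential survival with group medians 9.2 / 18.8 months, 4PL JQ1
#' chemograms with group IC50s 2.3 / 39.22 uM, and ordinal Ki67 (0-4) and
#' differentiation (0-2) histology scores.
#'
#' @param n_patients number of samples (>= 2)
#' @param frac_high proportion of MYC-high samples in [0,1]; group sizes are
#'   assigned by exact quota `round(frac_high * n_patients)` so the 17/55
#'   split is reproduced exactly
#' @param n_myc_targets size of the MYC-target gene block (includes the 10
#'   up-markers)
#' @param n_background_genes genes with no group effect
#' @param panel_log2fc log2 fold change of the 10 up-markers in the high
#'   group and of the 6 down-markers in the low group; the remaining target
#'   block genes receive half this effect
#' @param noise_sd per-observation Gaussian SD on the log2 scale
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression
#'   distribution (RMA-like range)
#' @param surv_median_high,surv_median_low exponential survival medians, months
#' @param censor_rate proportion of records independently censored
#' @param ic50_high,ic50_low group JQ1 IC50s, uM
#' @param hill 4PL Hill slope
#' @param viab_noise_sd viability noise SD, percentage points
#' @param n_chemo_lines cell lines simulated per group
#' @param dose_min,dose_max,n_doses chemogram design: dose 0 plus
#'   `n_doses - 1` log-spaced doses in [dose_min, dose_max] uM
#' @param n_replicates viability replicates per dose
#' @param ki67_mean_high,ki67_mean_low,ki67_sd latent Gaussian for the
#'   ordinal Ki67 score (rounded and clipped to 0-4)
#' @param diff_mean_high,diff_mean_low,diff_sd latent Gaussian for the
#'   ordinal differentiation score (rounded and clipped to 0-2)
#' @param ct0 qPCR intercept: Ct at unit linear expression
#' @param ct_ref mean Ct of the abundant reference transcript (28S rRNA role)
#' @param qpcr_noise_sd technical Ct noise SD
#' @param seed integer seed; all cohort randomness derives from it
#'
#' @return a validated list of class `CohortConfig`
#' @seealso [simulateCohort()]
#' @export
cohortConfig <- function(n_patients = 55, frac_high = 17 / 55,
                         n_myc_targets = 239, n_background_genes = 745,
                         panel_log2fc = 2.0, noise_sd = 0.5,
                         baseline_mean = 7, baseline_sd = 1.5,
                         surv_median_high = 9.2, surv_median_low = 18.8,
                         censor_rate = 0,
                         ic50_high = 2.3, ic50_low = 39.22, hill = 1.0,
                         viab_noise_sd = 2.0, n_chemo_lines = 4,
                         dose_min = 0.1, dose_max = 30, n_doses = 10,
                         n_replicates = 3,
                         ki67_mean_high = 2.88, ki67_mean_low = 2.06,
                         ki67_sd = 1.0,
                         diff_mean_high = 0.77, diff_mean_low = 1.82,
                         diff_sd = 0.6,
                         ct0 = 30, ct_ref = 13, qpcr_noise_sd = 0.15,
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_patients", "n_myc_targets", "n_background_genes",
              "n_chemo_lines", "n_doses", "n_replicates")
  for (f in counts)
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("'", f, "' must be a positive integer")
  if (cfg$n_patients < 2) stop("'n_patients' must be at least 2")
  if (cfg$frac_high < 0 || cfg$frac_high > 1)
    stop("'frac_high' must lie in [0, 1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("'censor_rate' must lie in [0, 1]")
  pos <- c("surv_median_high", "surv_median_low", "ic50_high", "ic50_low",
           "hill", "noise_sd", "baseline_sd", "dose_min", "dose_max")
  for (f in pos) if (cfg[[f]] <= 0) stop("'", f, "' must be > 0")
  if (cfg$n_myc_targets < 10)
    stop("'n_myc_targets' must be >= 10 (it contains the 10 up-markers)")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "CohortConfig"
  cfg
}

.asConfig <- function(config) {
  if (inherits(config, "CohortConfig")) config else do.call(cohortConfig, config)
}

#' Gene identifiers of the synthetic MYC-target block
#'
#' The designated target block: the 10 published up-markers followed by
#' synthetic filler targets (`MYCT001`, ...) up to `n_myc_targets` genes.
#'
#' @param config a [cohortConfig()]
#' @return character vector of gene ids
#' @export
mycTargetGenes <- function(config = cohortConfig()) {
  config <- .asConfig(config)
  panel <- mycMarkerPanel()
  extra <- config$n_myc_targets - length(upGenes(panel))
  c(upGenes(panel),
    if (extra > 0) sprintf("MYCT%03d", seq_len(extra)))
}

.derivedSeeds <- function(seed, n = 6L) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a full synthetic PDX cohort
#'
#' Draws a genes-by-samples linear-scale expression matrix with a planted
#' MYC-high/MYC-low group structure, plus matched survival records, ordinal
#' histology scores, per-group chemograms, and a marker qPCR Ct table.
#' Log2-scale expression is `baseline_g + effect_g * 1(high) + N(0, noise_sd)`
#' and the stored linear values are `2^` that. Group sizes follow the exact
#' quota `round(frac_high * n)`; the draw is bit-reproducible given the seed.
#'
#' @param config a [cohortConfig()] (or a list of its arguments)
#' @return a \linkS4class{MycCohort}
#' @examples
#' ch <- simulateCohort(cohortConfig(n_patients = 12, seed = 3))
#' table(trueLabels(ch))
#' @export
simulateCohort <- function(config = cohortConfig()) {
  config <- .asConfig(config)
  seeds <- .derivedSeeds(config$seed)

  n <- config$n_patients
  nHigh <- round(config$frac_high * n)
  if (nHigh == 0L || nHigh == n)
    warning("frac_high * n_patients rounds to ", nHigh,
            ": cohort has a single group")

  set.seed(seeds[1])
  labels <- rep("low", n)
  labels[sample.int(n, nHigh)] <- "high"
  labels <- factor(labels, levels = c("high", "low"))
  sampleIds <- sprintf("PDX%03d", seq_len(n))

  panel <- mycMarkerPanel()
  targets <- mycTargetGenes(config)
  genes <- c(targets, downGenes(panel),
             if (config$n_background_genes > 0)
               sprintf("BG%04d", seq_len(config$n_background_genes)))

  effHigh <- numeric(length(genes))
  names(effHigh) <- genes
  effHigh[upGenes(panel)] <- config$panel_log2fc
  effHigh[setdiff(targets, upGenes(panel))] <- config$panel_log2fc / 2
  effHigh[downGenes(panel)] <- -config$panel_log2fc  # elevated in low group

  set.seed(seeds[2])
  baseline <- stats::rnorm(length(genes), config$baseline_mean,
                           config$baseline_sd)
  log2expr <- baseline +
    outer(effHigh, as.numeric(labels == "high")) +
    matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
           nrow = length(genes))
  dimnames(log2expr) <- list(genes, sampleIds)
  exprs <- 2^log2expr

  surv <- simulateSurvival(labels, config, seed = seeds[3])
  histo <- simulateHistoScores(labels, config, seed = seeds[4])
  chem <- simulateChemograms(config, seed = seeds[5])
  qp <- simulateQpcr(exprs, config, seed = seeds[6])

  cd <- S4Vectors::DataFrame(
    group = labels, time_months = surv$time_months, event = surv$event,
    ki67 = histo$ki67, diff = histo$diff, row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd,
    metadata = list(scale = "linear", myc_targets = targets,
                    panel = panel))
  methods::new("MycCohort", se, chemograms = chem, qpcr = qp,
               simConfig = unclass(config))
}

#' Simulate group-wise exponential survival records
#'
#' Event times are exponential with rate `log(2) / median` for the group's
#' configured median. Each record is independently censored with probability
#' `censor_rate`; a censored record is observed at a Uniform(0, T) fraction
#' of its latent event time, so the censoring proportion is exact.
#'
#' @param labels factor/character of "high"/"low" group labels
#' @param config a [cohortConfig()]
#' @param seed optional integer seed
#' @return data.frame with time_months, event (1 event / 0 censored), group;
#'   attribute `all_censored` flags the degenerate censor_rate = 1 case
#' @export
simulateSurvival <- function(labels, config = cohortConfig(), seed = NULL) {
  config <- .asConfig(config)
  if (length(labels) == 0) stop("'labels' must be nonempty")
  if (config$surv_median_high <= 0 || config$surv_median_low <= 0)
    stop("survival medians must be > 0")
  if (!is.null(seed)) set.seed(seed)
  med <- ifelse(labels == "high",
                config$surv_median_high, config$surv_median_low)
  t0 <- stats::rexp(length(labels), rate = log(2) / med)
  cens <- stats::runif(length(labels)) < config$censor_rate
  time <- ifelse(cens, pmax(stats::runif(length(labels)) * t0,
                            .Machine$double.eps), t0)
  out <- data.frame(time_months = time, event = as.integer(!cens),
                    group = as.character(labels), stringsAsFactors = FALSE)
  if (all(cens)) {
    attr(out, "all_censored") <- TRUE
    warning("all records censored (censor_rate = ", config$censor_rate, ")")
  }
  out
}

#' Chemogram dose design
#'
#' Dose 0 (vehicle) plus `n_doses - 1` log-spaced concentrations spanning
#' `[dose_min, dose_max]` uM.
#'
#' @param config a [cohortConfig()]
#' @return numeric vector of doses, uM
#' @export
chemogramDoses <- function(config = cohortConfig()) {
  config <- .asConfig(config)
  c(0, 10^seq(log10(config$dose_min), log10(config$dose_max),
              length.out = config$n_doses - 1L))
}

#' Simulate one dose-response chemogram
#'
#' Replicate viabilities follow a four-parameter logistic curve
#' (bottom 0, top 100, configured Hill slope and group IC50) with additive
#' Gaussian noise in percentage points, clipped at 0.
#'
#' @param label "high" or "low" (selects the group IC50)
#' @param config a [cohortConfig()]
#' @param cell_id identifier for the simulated line
#' @param seed optional integer seed
#' @return data.frame with cell_id, group, dose_uM, replicate, viability_pct
#' @export
simulateChemogram <- function(label, config = cohortConfig(),
                              cell_id = paste0("CL_", label), seed = NULL) {
  config <- .asConfig(config)
  label <- match.arg(label, c("high", "low"))
  if (!is.null(seed)) set.seed(seed)
  ic50 <- if (label == "high") config$ic50_high else config$ic50_low
  doses <- chemogramDoses(config)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      dose_uM = doses)
  v <- fourPL(grid$dose_uM, bottom = 0, top = 100,
              hill = config$hill, ic50 = ic50)
  if (config$viab_noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, config$viab_noise_sd)
  data.frame(cell_id = cell_id, group = label, dose_uM = grid$dose_uM,
             replicate = grid$replicate,
             viability_pct = pmax(v, 0), stringsAsFactors = FALSE)
}

#' Simulate chemograms for a panel of cell lines
#'
#' `n_chemo_lines` MYC-high and `n_chemo_lines` MYC-low lines (the study
#' screened 4 + 4).
#'
#' @inheritParams simulateChemogram
#' @return long data.frame, one [simulateChemogram()] block per line
#' @export
simulateChemograms <- function(config = cohortConfig(), seed = NULL) {
  config <- .asConfig(config)
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(2L * config$n_chemo_lines), function(i) {
    lab <- if (i <= config$n_chemo_lines) "high" else "low"
    simulateChemogram(lab, config,
                      cell_id = sprintf("CL%02d_%s", i, lab))
  })
  do.call(rbind, blocks)
}

#' Simulate ordinal histology scores
#'
#' Ki67 (0-4) and differentiation (0-2) scores are rounded, clipped draws
#' from group-specific latent Gaussians.
#'
#' @inheritParams simulateSurvival
#' @return data.frame with ki67, diff (integer), group
#' @export
simulateHistoScores <- function(labels, config = cohortConfig(), seed = NULL) {
  config <- .asConfig(config)
  if (length(labels) == 0) stop("'labels' must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  high <- labels == "high"
  n <- length(labels)
  ki <- stats::rnorm(n, ifelse(high, config$ki67_mean_high,
                               config$ki67_mean_low), config$ki67_sd)
  df <- stats::rnorm(n, ifelse(high, config$diff_mean_high,
                               config$diff_mean_low), config$diff_sd)
  data.frame(ki67 = as.integer(pmin(4, pmax(0, round(ki)))),
             diff = as.integer(pmin(2, pmax(0, round(df)))),
             group = as.character(labels), stringsAsFactors = FALSE)
}

#' Simulate a marker qPCR Ct table
#'
#' For each of the 16 panel markers, Ct = ct0 - log2(linear expression) +
#' N(0, qpcr_noise_sd); the reference transcript (28S rRNA role, constant
#' mean `ct_ref`) is appended per sample, so delta-delta-Ct relative
#' quantities recapitulate the expression fold structure.
#'
#' @param exprs linear-scale genes-by-samples matrix covering the panel
#' @param config a [cohortConfig()]
#' @param panel a \linkS4class{MarkerPanel}
#' @param seed optional integer seed
#' @return long data.frame with sample_id, gene, ct
#' @export
simulateQpcr <- function(exprs, config = cohortConfig(),
                         panel = mycMarkerPanel(), seed = NULL) {
  config <- .asConfig(config)
  if (!is.null(seed)) set.seed(seed)
  markers <- c(upGenes(panel), downGenes(panel))
  missing <- setdiff(markers, rownames(exprs))
  if (length(missing))
    stop("panel marker(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- exprs[markers, , drop = FALSE]
  ct <- config$ct0 - log2(sub)
  if (config$qpcr_noise_sd > 0)
    ct <- ct + matrix(stats::rnorm(length(ct), 0, config$qpcr_noise_sd),
                      nrow = nrow(ct))
  ref <- config$ct_ref + stats::rnorm(ncol(sub), 0, config$qpcr_noise_sd)
  long <- data.frame(
    sample_id = rep(colnames(sub), each = nrow(sub) + 1L),
    gene = rep(c(markers, "RN28S"), times = ncol(sub)),
    ct = as.numeric(rbind(ct, ref)), stringsAsFactors = FALSE)
  long
}
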