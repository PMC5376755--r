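#' End-to-end stratification pipeline
#'
#' Runs the full analysis chain on one cohort: acquire (simulate or read)
#' -> unsupervised 2-group clustering on the MYC-target panel -> rank genes
#' -> derive the 16-marker panel -> ratio-signature scoring -> GSEA ->
#' survival statistics -> chemogram 4PL fits, then writes every stage
#' result plus a machine-readable summary JSON into `outDir`. All
#' randomness flows from the configured seeds; two runs with the same
#' configuration produce byte-identical summaries.
#'
#' @param config a list with exactly one of:
#'   \describe{
#'     \item{simulate}{list of [cohortConfig()] arguments (seed mandatory)}
#'     \item{expression}{path to an expression TSV/CSV/GCT, together with
#'       `scale` ("linear"/"log2"), `metadata` (CSV path, optional) and
#'       `chemograms` (CSV path, optional)}
#'   }
#'   plus optional fields: `targets` (GMT path; for simulated cohorts the
#'   generator's target block is the default), `panel` ("learn" to derive
#'   the markers, "default" for the published panel), `n_up`, `n_down`,
#'   `gmt` (gene sets for GSEA; defaults to the target block plus seeded
#'   random background sets), `n_perm` (default 1000), `gsea_seed`.
#' @param outDir output directory
#' @return invisibly, the summary list (also written as summary.json)
#' @export
runPipeline <- function(config, outDir) {
  hasSim <- !is.null(config$simulate)
  hasFiles <- !is.null(config$expression)
  if (hasSim == hasFiles)
    stop("config must contain exactly one of 'simulate' or 'expression'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message("[MycStratify] ", msg)
    log <<- c(log, msg)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  h <- configHash(config)
  say("config hash ", h)

  if (hasSim) {
    if (is.null(config$simulate$seed))
      stop("'simulate' block requires a seed")
    simCfg <- stage("simulate", do.call(cohortConfig, config$simulate))
    cohort <- stage("simulate", simulateCohort(simCfg))
    say("simulated cohort: ", ncol(cohort), " samples, seed ",
        simCfg$seed)
    se <- cohort
    chem <- chemograms(cohort)
    surv <- survivalData(cohort)
    targets <- S4Vectors::metadata(cohort)$myc_targets
    writeCohort(cohort, file.path(outDir, "cohort"))
  } else {
    se <- stage("read", readExpressionMatrix(
      config$expression, scale = config$scale %||% "linear"))
    say("read expression: ", nrow(se), " genes x ", ncol(se), " samples")
    chem <- if (!is.null(config$chemograms))
      utils::read.csv(config$chemograms, comment.char = "#",
                      stringsAsFactors = FALSE) else NULL
    surv <- if (!is.null(config$metadata)) {
      md <- stage("read", readSampleMetadata(config$metadata))
      unmatched <- setdiff(md$sample_id, colnames(se))
      if (length(unmatched))
        stop("metadata sample id(s) absent from expression: ",
             paste(unmatched, collapse = ", "))
      md
    } else NULL
    targets <- NULL
  }
  if (!is.null(config$targets)) targets <- unlist(readGmt(config$targets))
  if (is.null(targets)) stop("no MYC-target gene list available")

  clus <- stage("stratify", clusterMycActivity(se, targets))
  say("clustering: ", sum(clus$labels == "high"), " high / ",
      sum(clus$labels == "low"), " low")
  utils::write.csv(
    data.frame(sample_id = names(clus$labels),
               cluster_label = as.character(clus$labels)),
    file.path(outDir, "cluster_labels.csv"), row.names = FALSE)

  ranked <- stage("rank", rankGenes(se, clus$labels))
  utils::write.csv(ranked, file.path(outDir, "ranked_genes.csv"),
                   row.names = FALSE)

  panel <- if (identical(config$panel, "default")) mycMarkerPanel()
    else stage("panel", selectMarkerPanel(
      ranked, targets, config$n_up %||% 10, config$n_down %||% 6))
  jsonlite::write_json(
    list(up = upGenes(panel), down = downGenes(panel)),
    file.path(outDir, "panel.json"))

  scores <- stage("score", scoreSignature(se, panel))
  say("signature: ", sum(sigLabel(scores) == "MYC-high"), " MYC-high")
  utils::write.csv(signatureTable(scores, ratios = TRUE),
                   file.path(outDir, "signature_scores.csv"),
                   row.names = FALSE)

  collection <- if (!is.null(config$gmt)) readGmt(config$gmt)
    else .defaultGeneSets(targets, rownames(se),
                          seed = config$gsea_seed %||% 1L)
  collection <- filterGeneSets(collection, rownames(se))
  gsea <- stage("gsea", gseaSignificance(
    se, clus$labels, collection, nPerm = config$n_perm %||% 1000,
    seed = config$gsea_seed %||% 1L))
  utils::write.csv(gsea, file.path(outDir, "enrichment.csv"),
                   row.names = FALSE)

  survStats <- NULL
  if (!is.null(surv)) {
    sigGroup <- ifelse(sigLabel(scores) == "MYC-high", "high", "low")
    sdf <- data.frame(time_months = surv$time_months, event = surv$event,
                      group = sigGroup[match(surv$sample_id,
                                             names(sigScore(scores)))])
    survStats <- stage("survival", survivalSummary(sdf))
    say("survival: log-rank p = ", signif(survStats$p, 3))
  }

  chemStats <- NULL
  if (!is.null(chem) && nrow(chem)) {
    fits <- stage("chemogram", fitChemograms(chem))
    utils::write.csv(fits, file.path(outDir, "chemogram_fits.csv"),
                     row.names = FALSE)
    chemStats <- stage("chemogram", ic50GroupSummary(fits))
  }

  agreement <- if (hasSim) {
    truth <- ifelse(trueLabels(cohort) == "high", "MYC-high", "MYC-low")
    mean(as.character(sigLabel(scores)) == truth)
  } else NA

  summary <- list(
    tool = "MycStratify", version = .pkgVersion(), config_hash = h,
    n_samples = ncol(se),
    n_true_high = if (hasSim) sum(trueLabels(cohort) == "high") else NULL,
    n_cluster_high = sum(clus$labels == "high"),
    n_signature_high = sum(sigLabel(scores) == "MYC-high"),
    signature_agreement = agreement,
    panel = list(up = upGenes(panel), down = downGenes(panel)),
    survival = survStats,
    ic50 = if (!is.null(chemStats)) chemStats$table else NULL,
    gsea_top = gsea[order(gsea$pval)[seq_len(min(5, nrow(gsea)))],
                    c("set", "nes", "pval", "fdr")])
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(c(.stampLine(h), log), file.path(outDir, "run.log"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Built-in gene-set collection for simulated cohorts: the planted
# MYC-target block plus seeded random background sets (null references
# for the FDR pooling).
.defaultGeneSets <- function(targets, genes, nRandom = 10, size = 30,
                             seed = 1L) {
  set.seed(seed)
  bg <- setdiff(genes, targets)
  rand <- lapply(seq_len(nRandom), function(i)
    sample(bg, min(size, length(bg))))
  names(rand) <- sprintf("RANDOM_SET_%02d", seq_len(nRandom))
  c(list(MYC_TARGET_BLOCK = intersect(targets, genes)), rand)
}
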