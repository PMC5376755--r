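#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MarkerPanel: an ordered up/down marker gene panel
#'
#' Holds the two ordered marker lists of a ratio-based expression signature:
#' genes expected to be elevated in the MYC-high stratum (`upGenes`) and
#' genes expected to be elevated in the MYC-low stratum (`downGenes`).
#' The default panel returned by [mycMarkerPanel()] is the published
#' 16-marker JQ1-sensitivity panel (10 up, 6 down).
#'
#' @slot upGenes character vector of up-marker gene identifiers (length K >= 1)
#' @slot downGenes character vector of down-marker gene identifiers (length L >= 1)
#'
#' @seealso [mycMarkerPanel()], [scoreSignature()]
#' @export
setClass("MarkerPanel",
  representation(upGenes = "character", downGenes = "character"))

setValidity("MarkerPanel", function(object) {
  msg <- NULL
  if (length(object@upGenes) < 1L)   msg <- c(msg, "need at least one up-marker")
  if (length(object@downGenes) < 1L) msg <- c(msg, "need at least one down-marker")
  if (anyDuplicated(object@upGenes))   msg <- c(msg, "duplicated up-marker ids")
  if (anyDuplicated(object@downGenes)) msg <- c(msg, "duplicated down-marker ids")
  both <- intersect(object@upGenes, object@downGenes)
  if (length(both))
    msg <- c(msg, paste0("gene(s) in both lists: ", paste(both, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' SignatureScores: per-sample ratio-signature calls
#'
#' Result container of [scoreSignature()]. For each sample it stores the
#' K*L normalized expression ratios, the median ratio score, the
#' MYC-high/MYC-low call (score > 1 => MYC-high, strict), and a boundary
#' flag raised when the score is exactly 1.
#'
#' @slot ratios numeric matrix, one column per sample, K*L rows named
#'   "up/down" per ratio
#' @slot score named numeric vector of per-sample median ratios
#' @slot label factor with levels c("MYC-high","MYC-low")
#' @slot boundary logical, TRUE where score == 1 exactly
#' @slot panel the \linkS4class{MarkerPanel} used
#'
#' @export
setClass("SignatureScores",
  representation(ratios = "matrix", score = "numeric", label = "factor",
                 boundary = "logical", panel = "MarkerPanel"))

setValidity("SignatureScores", function(object) {
  n <- length(object@score)
  msg <- NULL
  if (ncol(object@ratios) != n) msg <- c(msg, "ratio columns != number of scores")
  if (length(object@label) != n) msg <- c(msg, "labels != number of scores")
  if (length(object@boundary) != n) msg <- c(msg, "boundary flags != number of scores")
  kl <- length(object@panel@upGenes) * length(object@panel@downGenes)
  if (nrow(object@ratios) != kl)
    msg <- c(msg, sprintf("expected %d ratios per sample, got %d", kl, nrow(object@ratios)))
  if (!identical(levels(object@label), c("MYC-high", "MYC-low")))
    msg <- c(msg, "label levels must be MYC-high, MYC-low")
  if (is.null(msg)) TRUE else msg
})

#' MycCohort: a simulated PDX expression cohort
#'
#' A \linkS4class{SummarizedExperiment} (assay \code{"exprs"}, linear scale)
#' extended with the auxiliary measurements the downstream analyses consume:
#' per-cell-line dose-response chemograms and a qPCR Ct table for the marker
#' panel. Sample-level truth (group label, survival, ordinal histology
#' scores) lives in \code{colData}.
#'
#' @slot chemograms data.frame with columns cell_id, group, dose_uM,
#'   replicate, viability_pct
#' @slot qpcr data.frame with columns sample_id, gene, ct (includes the
#'   reference gene)
#' @slot simConfig list, the generating configuration
#'
#' @seealso [simulateCohort()]
#' @export
setClass("MycCohort",
  contains = "SummarizedExperiment",
  representation(chemograms = "data.frame", qpcr = "data.frame",
                 simConfig = "list"))

setValidity("MycCohort", function(object) {
  msg <- NULL
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' missing")
  else if (any(SummarizedExperiment::assay(object, "exprs") <= 0))
    msg <- c(msg, "linear expression values must be strictly positive")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry 'group'")
  if (is.null(msg)) TRUE else msg
})
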