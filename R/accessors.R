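#' @rdname MarkerPanel-class
#' @aliases upGenes,MarkerPanel-method
setMethod("upGenes", "MarkerPanel", function(x) x@upGenes)

#' @rdname MarkerPanel-class
#' @aliases downGenes,MarkerPanel-method
setMethod("downGenes", "MarkerPanel", function(x) x@downGenes)

#' @rdname SignatureScores-class
#' @aliases sigScore,SignatureScores-method
setMethod("sigScore", "SignatureScores", function(x) x@score)

#' @rdname SignatureScores-class
#' @aliases sigLabel,SignatureScores-method
setMethod("sigLabel", "SignatureScores", function(x) x@label)

#' @rdname SignatureScores-class
#' @aliases sigRatios,SignatureScores-method
setMethod("sigRatios", "SignatureScores", function(x) x@ratios)

#' @rdname SignatureScores-class
#' @aliases boundaryFlag,SignatureScores-method
setMethod("boundaryFlag", "SignatureScores", function(x) x@boundary)

#' @rdname SignatureScores-class
#' @aliases upGenes,SignatureScores-method
setMethod("upGenes", "SignatureScores", function(x) x@panel@upGenes)

#' @rdname SignatureScores-class
#' @aliases downGenes,SignatureScores-method
setMethod("downGenes", "SignatureScores", function(x) x@panel@downGenes)

#' @rdname MycCohort-class
#' @aliases trueLabels,MycCohort-method
setMethod("trueLabels", "MycCohort", function(x)
  SummarizedExperiment::colData(x)$group)

#' @rdname MycCohort-class
#' @aliases survivalData,MycCohort-method
setMethod("survivalData", "MycCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = colnames(x), group = cd$group,
             time_months = cd$time_months, event = cd$event,
             stringsAsFactors = FALSE)
})

#' @rdname MycCohort-class
#' @aliases histoScores,MycCohort-method
setMethod("histoScores", "MycCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = colnames(x), group = cd$group,
             ki67 = cd$ki67, diff = cd$diff, stringsAsFactors = FALSE)
})

#' @rdname MycCohort-class
#' @aliases chemograms,MycCohort-method
setMethod("chemograms", "MycCohort", function(x) x@chemograms)

#' @rdname MycCohort-class
#' @aliases qpcrData,MycCohort-method
setMethod("qpcrData", "MycCohort", function(x) x@qpcr)

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel:", length(object@upGenes), "up /",
      length(object@downGenes), "down markers\n")
  cat("  up:  ", paste(object@upGenes, collapse = " "), "\n")
  cat("  down:", paste(object@downGenes, collapse = " "), "\n")
})

setMethod("show", "SignatureScores", function(object) {
  n <- length(object@score)
  tab <- table(object@label)
  cat("SignatureScores:", n, "samples,", nrow(object@ratios),
      "ratios per sample\n")
  cat(sprintf("  MYC-high: %d  MYC-low: %d  (boundary: %d)\n",
              tab[["MYC-high"]], tab[["MYC-low"]], sum(object@boundary)))
  cat("  score range:", signif(min(object@score), 4), "-",
      signif(max(object@score), 4), "\n")
})

setMethod("show", "MycCohort", function(object) {
  callNextMethod()
  tab <- table(trueLabels(object))
  cat(sprintf("true labels: %d high / %d low\n",
              tab[["high"]], tab[["low"]]))
  cat(sprintf("chemograms: %d rows; qPCR: %d rows\n",
              nrow(object@chemograms), nrow(object@qpcr)))
})
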