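#' @rdname MarkerPanel-class
#' @param x a MarkerPanel (or object carrying one)
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname SignatureScores-class
#' @export
setGeneric("sigScore", function(x) standardGeneric("sigScore"))

#' @rdname SignatureScores-class
#' @export
setGeneric("sigLabel", function(x) standardGeneric("sigLabel"))

#' @rdname SignatureScores-class
#' @export
setGeneric("sigRatios", function(x) standardGeneric("sigRatios"))

#' @rdname SignatureScores-class
#' @export
setGeneric("boundaryFlag", function(x) standardGeneric("boundaryFlag"))

#' @rdname MycCohort-class
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname MycCohort-class
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' @rdname MycCohort-class
#' @export
setGeneric("histoScores", function(x) standardGeneric("histoScores"))

#' @rdname MycCohort-class
#' @export
setGeneric("chemograms", function(x) standardGeneric("chemograms"))

#' @rdname MycCohort-class
#' @export
setGeneric("qpcrData", function(x) standardGeneric("qpcrData"))

#' Score samples with the ratio signature
#'
#' @param x expression input: a numeric genes-by-samples matrix, a
#'   \linkS4class{SummarizedExperiment}, or a \linkS4class{MycCohort}
#' @param panel a \linkS4class{MarkerPanel}; default [mycMarkerPanel()]
#' @param ... passed to methods (notably `scale`)
#' @return a \linkS4class{SignatureScores}
#' @export
setGeneric("scoreSignature",
  function(x, panel = mycMarkerPanel(), ...) standardGeneric("scoreSignature"))
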