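#' Construct a marker panel
#'
#' @param up,down ordered character vectors of up- and down-marker gene ids
#' @return a \linkS4class{MarkerPanel}
#' @export
MarkerPanel <- function(up, down) {
  methods::new("MarkerPanel", upGenes = as.character(up),
               downGenes = as.character(down))
}

#' The published 16-gene MYC-activity marker panel
#'
#' Ten transcripts elevated in MYC-high pancreatic tumors (all c-MYC
#' targets) and six transcripts elevated in MYC-low tumors. Ratios of the
#' mean-centered up/down markers separate the two strata.
#'
#' @return a \linkS4class{MarkerPanel} of 10 up + 6 down markers
#' @export
mycMarkerPanel <- function() {
  MarkerPanel(
    up = c("CDC20", "KPNA2", "PLK1", "SRM", "RFC4",
           "MCM2", "RUVBL2", "MAD2L1", "CCT4", "CAD"),
    down = c("VSIG2", "BCL2L15", "RAB25", "TXNIP", "CTSE", "ERN2"))
}

#' Mean-centered marker normalization
#'
#' Rescales each marker row of a linear-scale expression matrix to percent
#' of its cohort total: `out[i, a] = x[i, a] * 100 / sum_a x[i, a]`. Every
#' row of the result sums to 100 across samples, which makes the downstream
#' ratio classifier invariant to per-gene calibration (the property that
#' lets one panel serve microarray and qPCR input).
#'
#' Note the normalization is cohort-relative: adding or removing samples
#' changes the denominators, and with them other samples' normalized values.
#'
#' @param x numeric matrix, markers as rows, samples as columns; strictly
#'   positive linear-scale values
#' @return matrix of the same shape, rows summing to 100
#' @examples
#' meanCenterNormalize(matrix(c(2, 3, 5), 1, dimnames = list("g", NULL)))
#' @export
meanCenterNormalize <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) < 1) stop("need at least one sample")
  if (any(!is.finite(x)) || any(x < 0))
    stop("expression must be finite and nonnegative (linear scale)")
  tot <- rowSums(x)
  zero <- tot == 0
  if (any(zero))
    stop("marker(s) with zero total expression: ",
         paste(rownames(x)[zero], collapse = ", "))
  sweep(x, 1, tot / 100, "/")
}

#' Up/down normalized expression ratios for one sample or all samples
#'
#' For sample a, the ratio for up-marker i and down-marker j is
#' `r[i, j, a] = U[i, a] / D[j, a]` over the mean-centered normalized
#' matrices U and D; with the default 10 + 6 panel this yields 60 ratios
#' per sample.
#'
#' @param normU,normD normalized matrices from [meanCenterNormalize()] for
#'   the up- and down-marker lists; identical sample columns
#' @return matrix with K*L rows (named "up/down") and one column per sample
#' @export
signatureRatios <- function(normU, normD) {
  if (!identical(colnames(normU), colnames(normD)) ||
      ncol(normU) != ncol(normD))
    stop("up- and down-marker matrices must cover the same samples")
  if (any(normD == 0)) {
    bad <- rownames(normD)[apply(normD == 0, 1, any)]
    stop("down-marker dropout (normalized value 0): ",
         paste(bad, collapse = ", "))
  }
  K <- nrow(normU); L <- nrow(normD)
  idx <- expand.grid(i = seq_len(K), j = seq_len(L))
  r <- normU[idx$i, , drop = FALSE] / normD[idx$j, , drop = FALSE]
  rownames(r) <- paste(rownames(normU)[idx$i], rownames(normD)[idx$j],
                       sep = "/")
  r
}

#' Classify one sample from its ratio set
#'
#' The score is the median of the ratios (even counts: mean of the two
#' central order statistics). Scores strictly above 1 are called MYC-high,
#' strictly below 1 MYC-low; a score of exactly 1 satisfies neither strict
#' inequality and is reported MYC-low with the boundary flag raised.
#'
#' @param ratios numeric vector of positive finite ratios
#' @return list with score, label ("MYC-high"/"MYC-low"), boundary (logical)
#' @export
classifyRatios <- function(ratios) {
  if (length(ratios) == 0) stop("empty ratio list")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be finite and positive")
  m <- stats::median(ratios)
  list(score = m,
       label = if (m > 1) "MYC-high" else "MYC-low",
       boundary = m == 1)
}

.scoreMatrix <- function(x, panel, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(x)) x <- as.matrix(x)
  markers <- c(upGenes(panel), downGenes(panel))
  missing <- setdiff(markers, rownames(x))
  if (length(missing))
    stop("panel marker(s) missing from expression input: ",
         paste(missing, collapse = ", "))
  if (scale == "log2") x <- 2^x
  sub <- x[markers, , drop = FALSE]
  if (any(sub <= 0))
    stop("panel expression must be strictly positive on the linear scale; ",
         "clean zero/negative values explicitly before scoring")
  normU <- meanCenterNormalize(x[upGenes(panel), , drop = FALSE])
  normD <- meanCenterNormalize(x[downGenes(panel), , drop = FALSE])
  r <- signatureRatios(normU, normD)
  calls <- apply(r, 2, classifyRatios)
  score <- vapply(calls, `[[`, numeric(1), "score")
  methods::new("SignatureScores",
    ratios = r, score = score,
    label = factor(vapply(calls, `[[`, character(1), "label"),
                   levels = c("MYC-high", "MYC-low")),
    boundary = vapply(calls, `[[`, logical(1), "boundary"),
    panel = panel)
}

#' @describeIn scoreSignature score a genes-by-samples matrix; `scale`
#'   ("linear" or "log2") declares its units — log2 input is exponentiated
#'   (2^x) before the ratio math, which is defined on fold changes
#' @param scale "linear" (default) or "log2"
#' @export
setMethod("scoreSignature", "matrix",
  function(x, panel = mycMarkerPanel(), scale = c("linear", "log2"), ...)
    .scoreMatrix(x, panel, scale))

#' @describeIn scoreSignature score a SummarizedExperiment (assay 1); the
#'   scale tag is read from `metadata(x)$scale` unless given
#' @export
setMethod("scoreSignature", "SummarizedExperiment",
  function(x, panel = mycMarkerPanel(), scale = NULL, ...) {
    if (is.null(scale)) {
      scale <- S4Vectors::metadata(x)$scale
      if (is.null(scale))
        stop("no scale tag in metadata(x); pass scale = 'linear' or 'log2'")
    }
    .scoreMatrix(SummarizedExperiment::assay(x, 1L), panel, scale)
  })

#' Relative quantity by the delta-delta-Ct method
#'
#' `RQ = 2^-[(ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)]`, the
#' fold change of the target transcript in a sample relative to a
#' calibrator, each normalized to a reference transcript. RQ values are
#' linear-scale and feed [meanCenterNormalize()] unchanged.
#'
#' @param ct_target,ct_ref sample Ct of target and reference transcript
#' @param ct_target_cal,ct_ref_cal calibrator Ct of target and reference
#' @return relative quantity (positive)
#' @examples
#' ddctQuantity(24, 12, 26, 12)  # 4
#' @export
ddctQuantity <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  cts <- c(ct_target, ct_ref, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))
}

#' Score a qPCR Ct table with the ratio signature
#'
#' Converts a long Ct table (sample_id, gene, ct) to per-marker relative
#' quantities via [ddctQuantity()] — each marker normalized to the
#' reference transcript, calibrated against the mean Ct across samples —
#' and scores the resulting linear-scale quantity matrix. The calibrator
#' choice rescales each marker row by a constant and therefore cannot
#' change any call (per-gene scale invariance).
#'
#' @param ct data.frame with columns sample_id, gene, ct (one Ct per
#'   sample-gene pair; technical replicates should be averaged upstream)
#' @param panel a \linkS4class{MarkerPanel}
#' @param reference gene id of the reference transcript in `ct`
#' @return a \linkS4class{SignatureScores}
#' @export
scoreSignatureQpcr <- function(ct, panel = mycMarkerPanel(),
                               reference = "RN28S") {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  wide <- stats::xtabs(ct ~ gene + sample_id, data = ct) /
    pmax(stats::xtabs(~ gene + sample_id, data = ct), 1)
  wide <- as.matrix(unclass(wide))
  markers <- c(upGenes(panel), downGenes(panel))
  missing <- setdiff(c(markers, reference), rownames(wide))
  if (length(missing))
    stop("gene(s) missing from Ct table: ", paste(missing, collapse = ", "))
  ctRef <- wide[reference, ]
  rq <- sapply(colnames(wide), function(s)
    ddctQuantity(wide[markers, s], ctRef[s],
                 rowMeans(wide[markers, , drop = FALSE]), mean(ctRef)))
  rownames(rq) <- markers
  .scoreMatrix(rq, panel, scale = "linear")
}

#' Tidy per-sample signature table
#'
#' @param scores a \linkS4class{SignatureScores}
#' @param ratios include the per-sample ratio columns (wide)
#' @return data.frame with sample_id, score, label, boundary_flag and
#'   optionally one column per ratio
#' @export
signatureTable <- function(scores, ratios = FALSE) {
  out <- data.frame(sample_id = names(sigScore(scores)),
                    score = unname(sigScore(scores)),
                    label = as.character(sigLabel(scores)),
                    boundary_flag = boundaryFlag(scores),
                    stringsAsFactors = FALSE)
  if (ratios)
    out <- cbind(out, as.data.frame(t(sigRatios(scores))))
  rownames(out) <- NULL
  out
}
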