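#' Filter a gene-set collection against an expression matrix
#'
#' Each set is first intersected with the measured genes, then kept iff its
#' intersected size lies in `[minSize, maxSize]` (the conventional GSEA
#' 15-500 window).
#'
#' @param collection named list of character gene-id vectors
#' @param matrixGenes character vector of measured gene ids
#' @param minSize,maxSize inclusive size bounds after intersection
#' @return filtered named list (possibly empty, with a warning)
#' @export
filterGeneSets <- function(collection, matrixGenes, minSize = 15,
                           maxSize = 500) {
  out <- lapply(collection, intersect, y = matrixGenes)
  keep <- vapply(out, function(s)
    length(s) >= minSize && length(s) <= maxSize, logical(1))
  out <- out[keep]
  if (length(out) == 0)
    warning("no gene set left after size filtering")
  out
}

#' Weighted GSEA enrichment score
#'
#' Kolmogorov-Smirnov-like running-sum statistic over a ranked gene list.
#' Walking down the ranking, set members ("hits") advance the sum by
#' `|metric|^p / sum_set |metric|^p` and non-members retreat it by
#' `1 / (N - set size)`; the ES is the running sum's signed maximum
#' deviation from zero. `p = 1` is the default weighting.
#'
#' @param stats named numeric vector of ranking-metric values; sorted in
#'   decreasing order internally
#' @param geneSet character vector of member gene ids (a strict subset of
#'   `names(stats)`)
#' @param p weighting exponent
#' @return list: `es` in [-1, 1], `running` (the full running-sum profile,
#'   named by gene in ranked order)
#' @export
enrichmentScore <- function(stats, geneSet, p = 1) {
  if (is.null(names(stats))) stop("'stats' must be named by gene")
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% geneSet
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no member in the ranked list")
  if (nh == length(stats))
    stop("gene set covers the whole ranked list (miss step undefined)")
  w <- abs(stats)^p
  sw <- sum(w[hit])
  if (sw == 0) stop("all set members carry zero metric weight")
  step <- ifelse(hit, w / sw, -1 / (length(stats) - nh))
  running <- cumsum(step)
  # signed maximum deviation; at a magnitude tie report the positive one
  es <- if (abs(max(running)) >= abs(min(running))) max(running)
        else min(running)
  list(es = unname(es), running = stats::setNames(running, names(stats)))
}

.gseaMetric <- function(x, high) {
  t <- .rowWelch(x, high)$t
  t[!is.finite(t)] <- 0
  t
}

.esVector <- function(stats, sets, p) {
  vapply(sets, function(s) enrichmentScore(stats, s, p)$es, numeric(1))
}

#' Phenotype-permutation GSEA significance
#'
#' Ranks genes by the Welch t statistic between the high and low strata,
#' computes the weighted [enrichmentScore()] per gene set, and builds the
#' null by permuting sample labels and re-ranking (`nPerm` times, the
#' conventional 1,000 by default). Per set, NES is the ES divided by the
#' mean |null ES| of matching sign; the nominal p is the add-one
#' permutation estimate among same-sign nulls; the FDR q follows the
#' pooled-NES procedure (fraction of null NES as extreme, over the
#' fraction of observed NES as extreme, capped at 1).
#'
#' @param x genes-by-samples log2 expression matrix (or
#'   SummarizedExperiment, log2-transformed internally)
#' @param labels "high"/"low" per sample (>= 3 per group)
#' @param collection named list of gene-id vectors (pre-filter with
#'   [filterGeneSets()])
#' @param nPerm number of label permutations (>= 1)
#' @param p weighting exponent of the enrichment statistic
#' @param seed optional integer seed for the permutation stream
#' @return data.frame: set, size, es, nes, pval, fdr
#' @export
gseaSignificance <- function(x, labels, collection, nPerm = 1000, p = 1,
                             seed = NULL) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- log2(SummarizedExperiment::assay(x, 1L))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nPerm < 1) stop("'nPerm' must be >= 1")
  high <- labels == "high"
  if (sum(high) < 3 || sum(!high) < 3)
    stop("phenotype permutation needs >= 3 samples per group")
  if (length(collection) == 0) stop("empty gene-set collection")
  sets <- lapply(collection, intersect, y = rownames(x))
  sizes <- lengths(sets)
  if (any(sizes == 0))
    stop("gene set(s) with no measured member: ",
         paste(names(sets)[sizes == 0], collapse = ", "))

  obs <- .esVector(.gseaMetric(x, high), sets, p)

  if (!is.null(seed)) set.seed(seed)
  nullES <- matrix(NA_real_, nPerm, length(sets),
                   dimnames = list(NULL, names(sets)))
  for (b in seq_len(nPerm)) {
    permHigh <- rep(FALSE, length(high))
    permHigh[sample.int(length(high), sum(high))] <- TRUE
    nullES[b, ] <- .esVector(.gseaMetric(x, permHigh), sets, p)
  }

  normalize <- function(es, null) {
    # sign-matched mean-|ES| normalization
    ref <- if (es >= 0) null[null >= 0] else null[null < 0]
    if (length(ref) == 0) return(NA_real_)
    es / mean(abs(ref))
  }
  nes <- mapply(function(i) normalize(obs[i], nullES[, i]),
                seq_along(sets))
  nullNES <- sapply(seq_along(sets), function(i) {
    null <- nullES[, i]
    pos <- null >= 0
    out <- null
    if (any(pos)) out[pos] <- null[pos] / mean(abs(null[pos]))
    if (any(!pos)) out[!pos] <- null[!pos] / mean(abs(null[!pos]))
    out
  })

  pval <- vapply(seq_along(sets), function(i) {
    null <- nullES[, i]
    same <- if (obs[i] >= 0) null >= 0 else null < 0
    (1 + sum(abs(null[same]) >= abs(obs[i]))) / (1 + sum(same))
  }, numeric(1))

  pooledNull <- as.numeric(nullNES)
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pooledNull[pooledNull >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i], na.rm = TRUE)
    } else {
      num <- mean(pooledNull[pooledNull < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i], na.rm = TRUE)
    }
    if (is.nan(num)) num <- 0
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set = names(sets), size = as.integer(sizes), es = obs,
             nes = nes, pval = pval, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}
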