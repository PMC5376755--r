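#' Unsupervised MYC-activity stratification
#'
#' Clusters samples on the expression of a MYC-target gene panel:
#' Euclidean distances between samples over the panel's log2 expression,
#' complete-linkage agglomeration, and a cut into two clusters. The cluster
#' with the greater mean panel expression is labeled "high".
#'
#' @param x genes-by-samples log2 expression matrix (RMA-like), or a
#'   \linkS4class{SummarizedExperiment}/\linkS4class{MycCohort} whose
#'   linear assay is log2-transformed internally
#' @param targets character vector of MYC-target gene ids; unresolved ids
#'   are reported in the result, not silently dropped
#' @return list of class `mycClustering`: `labels` (factor high/low, named
#'   by sample), `tree` (the hclust object), `unresolved` (target ids not
#'   in the matrix), `panelMeans` (per-cluster mean panel expression)
#' @export
clusterMycActivity <- function(x, targets) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- log2(SummarizedExperiment::assay(x, 1L))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(targets) == 0) stop("'targets' must be nonempty")
  if (ncol(x) < 3) stop("need at least 3 samples to cluster")
  unresolved <- setdiff(targets, rownames(x))
  found <- intersect(targets, rownames(x))
  if (length(found) == 0) stop("no target gene found in the matrix")
  sub <- x[found, , drop = FALSE]
  d <- stats::dist(t(sub), method = "euclidean")
  if (all(d == 0)) stop("all samples identical over the target panel")
  tree <- stats::hclust(d, method = "complete")
  cut2 <- stats::cutree(tree, k = 2)
  means <- tapply(colMeans(sub), cut2, mean)
  highCluster <- as.integer(names(means)[which.max(means)])
  labels <- factor(ifelse(cut2 == highCluster, "high", "low"),
                   levels = c("high", "low"))
  names(labels) <- colnames(x)
  structure(list(labels = labels, tree = tree, unresolved = unresolved,
                 panelMeans = means),
            class = "mycClustering")
}

#' @export
print.mycClustering <- function(x, ...) {
  tab <- table(x$labels)
  cat("MYC-activity 2-group clustering (complete linkage, Euclidean)\n")
  cat(sprintf("  high: %d  low: %d samples\n", tab[["high"]], tab[["low"]]))
  if (length(x$unresolved))
    cat("  unresolved target ids:", length(x$unresolved), "\n")
  invisible(x)
}

# Vectorised per-row Welch t over a genes-by-samples matrix. This is the
# hot path of phenotype-permutation GSEA; stats::t.test is the per-gene
# oracle in the test suite.
.rowWelch <- function(x, high) {
  nA <- sum(high); nB <- sum(!high)
  xa <- x[, high, drop = FALSE]; xb <- x[, !high, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (nA - 1)
  vb <- rowSums((xb - mb)^2) / (nB - 1)
  se2 <- va / nA + vb / nB
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / nA)^2 / (nA - 1) + (vb / nB)^2 / (nB - 1))
  list(t = t, df = df, meanDiff = ma - mb)
}

#' Rank genes by differential expression between the two strata
#'
#' Per-gene two-sample test of high vs low on log2 expression: Welch's
#' unequal-variance t (default) or the Wilcoxon rank-sum alternative.
#' Two-sided p-values receive Benjamini-Hochberg q-values. Genes with zero
#' variance in both groups have an undefined statistic; they are flagged
#' (`degenerate`) and ranked last.
#'
#' @param x genes-by-samples log2 expression matrix (or SummarizedExperiment,
#'   log2-transformed internally)
#' @param labels factor/character "high"/"low" per sample
#' @param method "welch" or "wilcoxon"
#' @return data.frame sorted by t (descending): gene, t, p, q, meanDiff,
#'   direction ("up"/"down" in high), degenerate
#' @export
rankGenes <- function(x, labels, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (methods::is(x, "SummarizedExperiment"))
    x <- log2(SummarizedExperiment::assay(x, 1L))
  if (!is.matrix(x)) x <- as.matrix(x)
  high <- labels == "high"
  if (sum(high) < 2 || sum(!high) < 2)
    stop("each group needs at least 2 samples")
  if (method == "welch") {
    w <- .rowWelch(x, high)
    t <- w$t; df <- w$df; meanDiff <- w$meanDiff
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    meanDiff <- rowMeans(x[, high, drop = FALSE]) -
      rowMeans(x[, !high, drop = FALSE])
    wt <- apply(x, 1, function(g) {
      ww <- suppressWarnings(stats::wilcox.test(g[high], g[!high]))
      c(ww$statistic, ww$p.value)
    })
    # signed standardized U so larger-in-high ranks first, as for t
    nA <- sum(high); nB <- sum(!high)
    t <- (wt[1, ] - nA * nB / 2) / sqrt(nA * nB * (nA + nB + 1) / 12)
    p <- wt[2, ]
  }
  degenerate <- !is.finite(t)
  p[degenerate] <- NA_real_
  out <- data.frame(gene = rownames(x), t = t, p = p,
                    q = bhAdjust(p), meanDiff = meanDiff,
                    direction = ifelse(meanDiff >= 0, "up", "down"),
                    degenerate = degenerate, stringsAsFactors = FALSE)
  out <- out[order(degenerate, -ifelse(degenerate, -Inf, t)), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{k >= rank(i)} p_(k) * m / k`, capped at 1 (delegates to
#' [stats::p.adjust()]); NA p-values propagate.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values, same length
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Derive the up/down marker panel from a ranked gene table
#'
#' Up-markers: the `nUp` top-ranked genes increased in the high group,
#' restricted to the MYC-target list. Down-markers: the `nDown` top-ranked
#' genes decreased in the high group, drawn from the whole matrix.
#'
#' @param ranked a [rankGenes()] table over the whole transcriptome
#' @param mycTargets character vector of MYC-target gene ids
#' @param nUp,nDown panel sizes (published panel: 10 and 6)
#' @return a \linkS4class{MarkerPanel}
#' @export
selectMarkerPanel <- function(ranked, mycTargets, nUp = 10, nDown = 6) {
  ok <- !ranked$degenerate
  upPool <- ranked[ok & ranked$gene %in% mycTargets & ranked$t > 0, ]
  downPool <- ranked[ok & ranked$t < 0, ]
  downPool <- downPool[order(downPool$t), ]
  if (nrow(upPool) < nUp)
    stop(sprintf("only %d up-candidate target genes for a panel of %d",
                 nrow(upPool), nUp))
  if (nrow(downPool) < nDown)
    stop(sprintf("only %d down-candidate genes for a panel of %d",
                 nrow(downPool), nDown))
  MarkerPanel(up = upPool$gene[seq_len(nUp)],
              down = downPool$gene[seq_len(nDown)])
}

#' Count target genes increased in the high stratum
#'
#' Convenience summary: targets with positive mean difference (high - low)
#' and BH q at or below `qMax`. The published per-gene criterion behind the
#' analogous cohort count is not fully specified; this is one reasonable
#' reading, with no equivalence claim.
#'
#' @param ranked a [rankGenes()] table
#' @param targets target gene ids
#' @param qMax q-value cutoff
#' @return integer count
#' @export
countIncreased <- function(ranked, targets, qMax = 0.05) {
  sub <- ranked[ranked$gene %in% targets & !ranked$degenerate, ]
  sum(sub$meanDiff > 0 & !is.na(sub$q) & sub$q <= qMax)
}
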