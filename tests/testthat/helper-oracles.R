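# Independent oracles used across the suite. Each is a deliberately
# naive reference implementation, kept separate from the package paths
# it checks.

# Brute-force agglomerative complete linkage: returns the 2-cluster
# partition as an integer vector. Ties broken by the lowest merged-index
# pair.
oracleCompleteLinkage2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 2) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      link <- max(d[clusters[[i]], clusters[[j]]])
      if (is.null(best) || link < best$link)
        best <- list(i = i, j = j, link = link)
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  part <- integer(n)
  for (k in seq_along(clusters)) part[clusters[[k]]] <- k
  part
}

# Step-up BH directly from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Textbook Welch t from the closed form.
oracleWelchT <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

# GSEA running sum from the definition, plain loop.
oracleES <- function(stats, geneSet, p = 1) {
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% geneSet
  sw <- sum(abs(stats[hit])^p)
  running <- 0; best <- 0
  for (i in seq_along(stats)) {
    running <- running + if (hit[i]) abs(stats[i])^p / sw else
      -1 / (length(stats) - sum(hit))
    if (abs(running) > abs(best) ||
        (abs(running) == abs(best) && running > best)) best <- running
  }
  unname(best)
}

# Row-wise Welch metric from the oracle (independent of the package's
# vectorised path).
oracleRowWelch <- function(m, high) {
  apply(m, 1, function(g) oracleWelchT(g[high], g[!high]))
}

# Two-partition agreement invariant to label switching.
partitionAgreement <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  max(mean(a == b), mean(a == 3L - b))
}

# Adjusted Rand index for two partitions.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# Small panel-complete expression fixture: the 16 default markers plus
# background genes, planted two-group structure, linear scale.
makeToyCohortMatrix <- function(nHigh = 5, nLow = 8, log2fc = 2,
                                noise = 0.3, nBackground = 20, seed = 42) {
  set.seed(seed)
  panel <- mycMarkerPanel()
  genes <- c(upGenes(panel), downGenes(panel),
             sprintf("BG%02d", seq_len(nBackground)))
  n <- nHigh + nLow
  labels <- rep(c("high", "low"), c(nHigh, nLow))
  eff <- c(rep(log2fc, 10), rep(-log2fc, 6), rep(0, nBackground))
  base <- rnorm(length(genes), 7, 1)
  m <- 2^(base + outer(eff, as.numeric(labels == "high")) +
            matrix(rnorm(length(genes) * n, 0, noise), length(genes)))
  dimnames(m) <- list(genes, sprintf("S%02d", seq_len(n)))
  attr(m, "labels") <- labels
  m
}
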