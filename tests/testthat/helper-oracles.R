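# Independent oracles used across the suite. Each deliberately uses a
# different algorithm than the implementation it checks.

# O(n^2) brute-force polynomial product, scalar accumulation
bruteConvolve <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p))
    for (j in seq_along(q))
      out[i + j - 1L] <- out[i + j - 1L] + p[i] * q[j]
  out
}

# Mass-shift spectrum of nC carbon atoms by explicit enumeration of all
# 2^nC heavy/light assignments
enumCarbonSpectrum <- function(nC, p13 = 0.0107) {
  out <- numeric(nC + 1L)
  for (state in 0:(2^nC - 1L)) {
    bits <- as.integer(intToBits(state))[seq_len(nC)]
    k <- sum(bits)
    out[k + 1L] <- out[k + 1L] + p13^k * (1 - p13)^(nC - k)
  }
  out
}

# Step-up BH by explicit sort / cumulative minimum
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- (n / seq_len(n)) * p[o]
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# One-sided (enrichment) hypergeometric tail by explicit summation
oracleHyperTail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(dhyper(kk, K, N - K, n))
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins, minimum-likelihood rule (relative tolerance on ties, the
# standard convention)
oracleFisherTwoSided <- function(nBoth, nAOnly, nBOnly, nNeither) {
  m1 <- nBoth + nAOnly          # row margin (event A carriers)
  c1 <- nBoth + nBOnly          # column margin (event B carriers)
  N <- nBoth + nAOnly + nBOnly + nNeither
  lo <- max(0L, c1 - (N - m1))
  hi <- min(m1, c1)
  support <- lo:hi
  probs <- dhyper(support, m1, N - m1, c1)
  dObs <- dhyper(nBoth, m1, N - m1, c1)
  sum(probs[probs <= dObs * (1 + 1e-7)])
}

# UPGMA merge heights by direct recomputation of average inter-cluster
# dissimilarity from the original distance matrix at every step
oracleUpgmaHeights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestH <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bestH) { bestH <- h; best <- c(i, j) }
      }
    heights <- c(heights, bestH)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

randomSimplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}
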