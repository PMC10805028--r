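# Independent oracles used by the tests. These deliberately re-derive the
# quantities through different algorithms than the package implementation.

# Optimal local alignment score with affine gaps by enumeration over chains
# of aligned residue pairs: any alignment decomposes into strictly
# increasing aligned pairs with one gap run per sequence between
# consecutive pairs, so maximizing over chains with that penalty yields the
# Smith-Waterman optimum. O(n^2 m^2), fine for short peptides.
sw_score_oracle <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  if (n == 0 || m == 0) return(0)
  pen <- function(d) if (d > 0) gap_open + gap_extend * d else 0
  g <- matrix(0, n, m)
  for (i in n:1) for (j in m:1) {
    best_ext <- 0
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        v <- g[i2, j2] - pen(i2 - i - 1) - pen(j2 - j - 1)
        if (v > best_ext) best_ext <- v
      }
    }
    g[i, j] <- mat[qa[i], sa[j]] + best_ext
  }
  max(0, max(g))
}

# Hand implementation of the published TMM recipe: reference sample by
# 75th-percentile count fraction, M/A over doubly-positive genes,
# rank-based double trimming, precision-weighted mean M, geometric-mean-1
# rescaling.
tmm_oracle <- function(mat, trim_M = 0.30, trim_A = 0.05, weighted = TRUE) {
  mat <- as.matrix(mat)
  lib <- colSums(mat)
  f75 <- vapply(seq_len(ncol(mat)), function(k)
    unname(quantile(mat[, k], 0.75)) / lib[k], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(mat)), function(k) {
    if (k == ref) return(1)
    obs <- mat[, k]; refv <- mat[, ref]
    nO <- lib[k]; nR <- lib[ref]
    keep0 <- obs > 0 & refv > 0
    M <- log2((obs / nO) / (refv / nR))[keep0]
    A <- (log2(obs / nO) + log2(refv / nR))[keep0] / 2
    v <- ((nO - obs) / (nO * obs) + (nR - refv) / (nR * refv))[keep0]
    n <- length(M)
    loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    fk <- if (weighted) 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep])) else
      2^mean(M[keep])
    if (!is.finite(fk) || is.na(fk)) 1 else fk
  }, numeric(1))
  f / exp(mean(log(f)))
}

# geTMM assembled from the oracle factors: RPK, per-million scaling by
# effective library size.
getmm_oracle <- function(counts, lengths, trim_M = 0.30, trim_A = 0.05,
                         count_floor = 5) {
  counts <- as.matrix(counts)
  counts[counts < count_floor] <- 0
  rpk <- counts / (lengths / 1000)
  f <- if (ncol(counts) >= 2) tmm_oracle(rpk, trim_M, trim_A) else 1
  sweep(rpk, 2, colSums(rpk) * f, "/") * 1e6
}
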