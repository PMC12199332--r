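# Independent reference implementations used as oracles. These stay
# deliberately naive (full matrices, explicit loops) and share no code
# with the package internals they check.

# O(n^3) adjacency-masked Ward: full Lance-Williams distance matrix on
# squared Euclidean distances, merges restricted to neighbouring
# interval clusters. Returns ordered segment sizes.
oracleConstrainedWard <- function(z, nClusters) {
  n <- nrow(z)
  D <- as.matrix(dist(z))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  members <- lapply(seq_len(n), identity)
  leftN <- c(NA, seq_len(n - 1))
  rightN <- c(seq_len(n - 1) + 1L, NA)
  k <- n
  while (k > nClusters) {
    bi <- NA; bj <- NA; bv <- Inf
    for (i in which(active)) {
      j <- rightN[i]
      if (!is.na(j) && D[i, j] < bv) { bv <- D[i, j]; bi <- i; bj <- j }
    }
    for (m in which(active)) {
      if (m == bi || m == bj) next
      D[bi, m] <- D[m, bi] <-
        ((size[bi] + size[m]) * D[bi, m] + (size[bj] + size[m]) * D[bj, m] -
           size[m] * D[bi, bj]) / (size[bi] + size[bj] + size[m])
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
    members[[bi]] <- c(members[[bi]], members[[bj]])
    rightN[bi] <- rightN[bj]
    if (!is.na(rightN[bj])) leftN[rightN[bj]] <- bi
    k <- k - 1L
  }
  lengths(members[active])
}

# Naive 1-D first-order Wasserstein via sorted quantile coupling on a
# common refinement (equal-mass interpolation at m points).
oracleW1 <- function(a, b, m = 20000L) {
  qa <- quantile(a, probs = (seq_len(m) - 0.5) / m, type = 1)
  qb <- quantile(b, probs = (seq_len(m) - 0.5) / m, type = 1)
  mean(abs(qa - qb))
}

# Brute-force loop precision/recall from explicit set comparison.
oraclePrf <- function(calls, reference) {
  k <- function(d) unique(paste(d$chrom, d$u, d$v))
  cs <- k(calls); rs <- k(reference)
  tp <- sum(cs %in% rs)
  p <- if (length(cs)) tp / length(cs) else 0
  r <- tp / length(rs)
  c(precision = p, recall = r,
    f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}
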