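# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: direct binomial-coefficient enumeration for the
# hypergeometric tail, Floyd-Warshall + BFS path counting for centralities,
# and a dense linear solve for the restart walk.

# P(X >= r), X ~ Hypergeometric(T, t, N), by direct enumeration of
# choose() terms in linear space (no logs, no tail flips).
enumHypergeomOracle <- function(T, t, N, r) {
  if (r <= 0) return(1)
  ks <- r:min(t, N)
  sum(choose(t, ks) * choose(T - t, N - ks)) / choose(T, N)
}

# Floyd-Warshall all-pairs shortest-path distances on an adjacency matrix.
fwDistances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Number of shortest paths between all pairs, by BFS-layer dynamic
# programming from each source.
countShortestPaths <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (w in ord) {
      if (w == s || !is.finite(D[s, w])) next
      preds <- which(A[, w] > 0 & D[s, ] == D[s, w] - 1)
      sigma[s, w] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# Brute-force degree / betweenness / closeness matching the package's
# definitions (betweenness normalised by (n-1)(n-2)/2; Wasserman-Faust
# closeness (r/(n-1)) * (r/sum d) over the r reachable nodes).
centralityOracle <- function(A) {
  n <- nrow(A)
  D <- fwDistances(A)
  sigma <- countShortestPaths(A, D)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- acc
  }
  btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- vapply(seq_len(n), function(v) {
    dd <- D[v, -v]
    reach <- sum(is.finite(dd))
    if (reach == 0) 0
    else (reach / (n - 1)) * (reach / sum(dd[is.finite(dd)]))
  }, 0)
  list(degree = rowSums(A > 0), betweenness = btw, closeness = clo)
}

# Direct fixed-point solve of p = (1-r) W p + r p0.
rwrSolveOracle <- function(W, p0, restart) {
  n <- nrow(W)
  drop(solve(diag(n) - (1 - restart) * W, restart * p0))
}

# Erdos-Renyi-ish random undirected graph as an adjacency matrix with named
# nodes; guaranteed at least one edge.
randomAdjacency <- function(n, p = 0.2) {
  repeat {
    A <- matrix(0L, n, n)
    up <- upper.tri(A)
    A[up] <- as.integer(stats::runif(sum(up)) < p)
    A <- A + t(A)
    if (sum(A) > 0) break
  }
  dimnames(A) <- list(sprintf("n%02d", seq_len(n)), sprintf("n%02d", seq_len(n)))
  A
}

graphFromAdjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Small, fast synthetic configuration shared by several tests.  The miRNA
# universe is kept large enough (~30 differentially expressed miRNAs) that
# five shared miRNAs stay clearly significant under the hypergeometric test.
smallConfig <- function(...) {
  syntheticConfig(nMrna = 120L, nLncrna = 30L, nMirna = 150L,
                  nPlantedCernaPairs = 16L, hubPairCount = 8L,
                  fracDe = 0.3, ...)
}

extdata <- function(f) system.file("extdata", f, package = "ceRNAnet")
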