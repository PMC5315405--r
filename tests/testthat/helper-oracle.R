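# Independent brute-force oracle for the bridging score: rebuilds the pruned
# coupling matrix explicitly, forms the normalized Laplacian with elementwise
# loops, takes a dense eigendecomposition, and decides how many eigenvalues
# to omit from the inverse sum by counting connected components with igraph
# (never with an eigenvalue threshold, keeping the route independent of the
# implementation under test).

oracle_softness <- function(sigma) {
  n <- nrow(sigma)
  deg <- rowSums(sigma)
  L <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) {
        L[a, b] <- if (deg[a] > 0) 1 else 0
      } else if (deg[a] > 0 && deg[b] > 0) {
        L[a, b] <- -sigma[a, b] / sqrt(deg[a] * deg[b])
      }
    }
  }
  lam <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  g <- igraph::graph_from_adjacency_matrix(sigma > 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  sum(1 / lam[(ncomp + 1):n])
}

oracle_bridging <- function(sigma, bonded) {
  n <- nrow(sigma)
  omega0 <- oracle_softness(sigma)
  vapply(seq_len(n), function(k) {
    s2 <- sigma
    for (j in seq_len(n)) {
      if (!bonded[k, j]) {
        s2[k, j] <- 0
        s2[j, k] <- 0
      }
    }
    oracle_softness(s2) - omega0
  }, numeric(1))
}
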