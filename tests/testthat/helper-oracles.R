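# Independent brute-force oracles for the clustering coefficients.

# Zhang-Horvath on cube-rooted positive weights, by explicit triple loops
zh_oracle <- function(W) {
  W[is.na(W)] <- 0; diag(W) <- 0
  A <- pmax(W, 0)^(1 / 3)
  n <- nrow(A)
  out <- numeric(n)
  for (u in 1:n) {
    num <- 0
    for (v in 1:n) for (w in 1:n) {
      if (v == u || w == u || v == w) next
      num <- num + A[u, v] * A[v, w] * A[w, u]
    }
    den <- sum(A[u, -u])^2 - sum(A[u, -u]^2)
    out[u] <- if (den > 0) num / den else 0
  }
  out
}

# ordinary unweighted clustering coefficient by triangle enumeration
unweighted_oracle <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (u in 1:n) {
    nb <- which(adj[u, ] > 0)
    k <- length(nb)
    if (k < 2) { out[u] <- 0; next }
    tri <- 0
    for (v in nb) for (w in nb) if (v != w && adj[v, w] > 0) tri <- tri + 1
    out[u] <- tri / (k * (k - 1))
  }
  out
}
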