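# Independent oracles used to pin expected values. These deliberately use
# different code paths (expand.grid enumeration, explicit double loops,
# BFS path counting) than the package implementations they check.

# energy by explicit double loop
bruteEnergy <- function(h, J, s) {
  e <- 0
  for (i in seq_along(h)) {
    e <- e - h[i] * s[i]
    for (j in seq_along(h)) e <- e - 0.5 * J[i, j] * s[i] * s[j]
  }
  e
}

# Boltzmann distribution by expand.grid enumeration, in the canonical
# order (-1 before +1, unit 1 most significant)
enumDistribution <- function(h, J) {
  N <- length(h)
  grid <- as.matrix(rev(expand.grid(rep(list(c(-1, 1)), N))))[, N:1, drop = FALSE]
  # rebuild canonical order explicitly: index from bits, unit 1 = MSB
  idx <- apply(grid, 1, function(s) sum(((s + 1) / 2) * 2^((N - 1):0))) + 1
  E <- apply(grid, 1, function(s) bruteEnergy(h, J, s))
  w <- exp(-E)
  p <- numeric(2^N)
  p[idx] <- w / sum(w)
  p
}

# covariance of observables by enumeration (FIM oracle)
enumFim <- function(h, J) {
  N <- length(h)
  p <- enumDistribution(h, J)
  pats <- patternMatrix(N)
  L <- N + N * (N - 1) / 2
  X <- matrix(0, 2^N, L)
  X[, 1:N] <- pats
  k <- N
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    k <- k + 1
    X[, k] <- pats[, i] * pats[, j]
  }
  mu <- colSums(X * p)
  Fm <- matrix(0, L, L)
  for (a in 1:L) for (b in 1:L)
    Fm[a, b] <- sum(X[, a] * X[, b] * p) - mu[a] * mu[b]
  Fm
}

# AUC by explicit pair counting with half-credit ties
aucPairCount <- function(values, labels) {
  st <- values[labels == "stiff"]
  sl <- values[labels == "sloppy"]
  tot <- 0
  for (a in st) for (b in sl)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(st) * length(sl))
}

# betweenness centrality by BFS shortest-path counting:
# BC(i) = sum over pairs k<l (k,l != i) of p(kl;i)/p(kl), where
# p(kl;i) = npaths(k,i)*npaths(i,l) when i lies on a shortest k-l path
bfsBetweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  for (src in 1:n) {
    dist[src, src] <- 0
    npaths[src, src] <- 1
    frontier <- src
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (u in which(adj[v, ] == 1)) {
        if (is.infinite(dist[src, u])) {
          dist[src, u] <- dist[src, v] + 1
          nxt <- c(nxt, u)
        }
        if (dist[src, u] == dist[src, v] + 1)
          npaths[src, u] <- npaths[src, u] + npaths[src, v]
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(n)
  for (i in 1:n) for (k in 1:(n - 1)) for (l in (k + 1):n) {
    if (k == i || l == i || is.infinite(dist[k, l])) next
    if (is.finite(dist[k, i]) && dist[k, i] + dist[i, l] == dist[k, l])
      bc[i] <- bc[i] + npaths[k, i] * npaths[i, l] / npaths[k, l]
  }
  bc
}

# toy dataset used across io/state/evoked tests
toyDataset <- function() {
  units <- data.frame(unit_id = 1:3, class = c("single", "single", "multi"))
  spikes <- data.frame(
    unit_id = c(1L, 1L, 2L),
    time_s = c(0.005, 0.012, 0.011))
  SpikeDataset(units = units, spikes = spikes, events = c(2.5, 5.0),
               duration = 10)
}
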