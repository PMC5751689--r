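# Independent brute-force oracles for the graph metrics, deliberately naive:
# Floyd-Warshall distances, exhaustive triangle counting, and direct
# evaluation of the efficiency definitions from the distance matrix.

fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_degree <- function(adj) as.integer(rowSums(adj != 0))

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] != 0) t_i <- t_i + 1
      }
    }
    2 * t_i / (k * (k - 1))
  })
}

oracle_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(rep(0, n))
  d <- fw_distances(adj)
  sapply(seq_len(n), function(i) sum(1 / d[i, -i]) / (n - 1))
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    d <- fw_distances(adj[nb, nb, drop = FALSE])
    tot <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) tot <- tot + 1 / d[a, b]
    tot / (k * (k - 1))
  })
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

as_adjacency <- function(m) binarize(make_corr(m), threshold = 0.5)

# Embed a binary matrix as a "correlation" matrix so binarize() at T = 0.5
# reproduces exactly its edges.
make_corr <- function(m) {
  r <- m * 0.9
  diag(r) <- 1
  r
}

# Closed-form squared magnitude of an analog Butterworth low-pass of given
# order, evaluated at frequency f for cutoff fc; the forward-backward digital
# filter attenuates at least this much at f < Nyquist.
butter_mag2 <- function(f, fc, order) 1 / (1 + (f / fc)^(2 * order))
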