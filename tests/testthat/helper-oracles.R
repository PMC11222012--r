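# Independent brute-force oracles used to cross-check the package's graph
# metrics and estimators. These deliberately share no code with the
# implementation: shortest paths by exhaustive Floyd-Warshall relaxation,
# clustering by explicit triangle enumeration.

# All-pairs shortest path lengths by Floyd-Warshall (Inf = unreachable).
fw_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

oracle_char_path <- function(adj) {
  d <- fw_dist(adj)
  v <- d[row(d) != col(d)]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0) NA_real_ else mean(v)
}

oracle_global_eff <- function(adj) {
  d <- fw_dist(adj)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# Mean local clustering by per-node triangle enumeration.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    total <- total + 2 * tri / (k * (k - 1))
  }
  total / n
}

# Mean global efficiency of each node's neighbor-induced subgraph.
oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    total <- total + oracle_global_eff(adj[nb, nb, drop = FALSE])
  }
  total / n
}

# Random Erdos-Renyi-style symmetric binary adjacency matrix.
rand_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Adjacency from named edges for small hand-built graphs.
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1L; a[e[2], e[1]] <- 1L }
  a
}

# Watts-Strogatz ring lattice with rewiring, as an independent construction.
ws_adjacency <- function(n, k, p, seed = 1) {
  g <- igraph::sample_smallworld(1, n, k / 2, p)
  a <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g), sparse = FALSE))
  storage.mode(a) <- "integer"
  a
}

# Periodogram-based fraction of signal energy inside [lo, hi) Hz.
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(fft(x))^2
  half <- 1:floor(n / 2 + 1)
  freqs <- (half - 1) * fs / n
  tot <- sum(sp[half])
  if (tot == 0) return(NA_real_)
  sum(sp[half][freqs >= lo & freqs < hi]) / tot
}

# A tiny well-separated three-class feature table for classifier tests.
separable_table <- function(n_per_class = 20, n_feat = 5, sep = 10, seed = 1) {
  set.seed(seed)
  states <- drivernet:::driving_states()
  rows <- lapply(seq_along(states), function(ci) {
    X <- matrix(rnorm(n_per_class * n_feat, mean = ci * sep), n_per_class)
    colnames(X) <- paste("sl", c("delta", "theta", "alpha", "beta", "delta")[seq_len(n_feat)],
                         c("V", "Cg", "Lg", "Eg", "El")[seq_len(n_feat)], sep = "_")
    data.frame(label = states[ci], subject = rep(1:4, length.out = n_per_class),
               epoch = seq_len(n_per_class), X, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
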