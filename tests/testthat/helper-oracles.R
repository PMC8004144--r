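# Independent oracles and graph builders used across the test files.
# Everything here is deliberately naive (explicit loops, Floyd-Warshall,
# refit-per-observation) so it shares no code path with the package.

# Floyd-Warshall topological distances from an adjacency matrix.
fw_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Distances by iterated boolean matrix powers of the adjacency matrix.
matpow_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  cur <- adj
  for (step in seq_len(n)) {
    new <- cur & !reach
    d[new & d > step] <- step
    reach <- reach | cur
    cur <- (cur %*% adj) > 0
  }
  d
}

# Hand-build a molecular_graph from an adjacency matrix (no package
# constructor involved beyond the class tag).
make_graph <- function(adj, props = NULL, coords = NULL,
                       elements = rep("C", nrow(adj))) {
  n <- nrow(adj)
  if (is.null(props))
    props <- matrix(1, n, 4, dimnames = list(NULL, c("m", "v", "e", "p")))
  structure(list(n_atoms = n, elements = elements,
                 adjacency = adj, dist = fw_dist(adj), props = props,
                 coords = coords, scaling = "test"),
            class = "molecular_graph")
}

# Random connected graph: spanning tree plus extra edges, random positive
# properties.
rand_graph <- function(n, seed, extra_edge_prob = 0.15) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)[-1]) {
    j <- sample.int(i - 1L, 1)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      if (!adj[i, j] && runif(1) < extra_edge_prob)
        adj[i, j] <- adj[j, i] <- TRUE
  props <- matrix(runif(4 * n, 0.5, 2), n, 4,
                  dimnames = list(NULL, c("m", "v", "e", "p")))
  make_graph(adj, props)
}

permute_graph <- function(g, perm) {
  make_graph(g$adjacency[perm, perm], g$props[perm, , drop = FALSE],
             if (is.null(g$coords)) NULL else g$coords[perm, , drop = FALSE],
             g$elements[perm])
}

# --- brute-force autocorrelation oracles (standard forms) ---

oracle_ats <- function(g, k, l) {
  p <- g$props[, k]; n <- g$n_atoms; s <- 0
  if (n >= 2)
    for (i in seq_len(n - 1))
      for (j in seq.int(i + 1, n))
        if (g$dist[i, j] == l) s <- s + p[i] * p[j]
  s
}

oracle_mats <- function(g, k, l) {
  p <- g$props[, k]; n <- g$n_atoms; pb <- mean(p)
  num <- 0; npairs <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && g$dist[i, j] == l) {
        num <- num + (p[i] - pb) * (p[j] - pb)
        npairs <- npairs + 1
      }
  L <- npairs / 2
  den <- sum((p - pb)^2)
  if (L == 0 || den < 1e-12) return(NA_real_)
  (num / (2 * L)) / (den / n)
}

oracle_gats <- function(g, k, l) {
  p <- g$props[, k]; n <- g$n_atoms; pb <- mean(p)
  num <- 0; L <- 0
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      if (g$dist[i, j] == l) {
        num <- num + (p[i] - p[j])^2
        L <- L + 1
      }
  den <- sum((p - pb)^2)
  if (L == 0 || den < 1e-12) return(NA_real_)
  (num / (2 * L)) / (den / (n - 1))
}

# --- explicit leave-one-out loop (refits with lm per observation) ---

oracle_loo <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    df_tr <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- lm(y ~ ., data = df_tr)
    pred <- unname(predict(fit, newdata = data.frame(X[i, , drop = FALSE])))
    press <- press + (y[i] - pred)^2
  }
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, s_cv = sqrt(press / (n - ncol(X) - 1)))
}

# 6-ring (benzene-like) graph with planar hexagon coordinates.
ring6_graph <- function(elements = rep("C", 6), r = 1.39) {
  adj <- matrix(FALSE, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; adj[i, j] <- adj[j, i] <- TRUE }
  ang <- seq(0, 300, 60) * pi / 180
  make_graph(adj, coords = cbind(r * cos(ang), r * sin(ang), 0),
             elements = elements)
}
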