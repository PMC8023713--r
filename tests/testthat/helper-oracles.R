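# Independent oracles, kept free of the package's own algorithms.

# Floyd-Warshall all-pairs shortest distances from a distance_graph's arc
# list (deliberately not Dijkstra).
fw_distances <- function(g) {
  arcs <- igraph::as_data_frame(g$graph, what = "edges")
  nodes <- igraph::V(g$graph)$name
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  directed <- igraph::is_directed(g$graph)
  for (r in seq_len(nrow(arcs))) {
    i <- arcs$from[r]; j <- arcs$to[r]
    D[i, j] <- min(D[i, j], arcs$dist[r])
    if (!directed) D[j, i] <- min(D[j, i], arcs$dist[r])
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Exact two-sided paired signed-rank p-value by full enumeration of all
# 2^n sign assignments (mid-ranks under ties), n small.
enum_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_lo <- mean(Ws <= W_obs + 1e-12)
  p_hi <- mean(Ws >= W_obs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}

# Influence zone by explicit linear-operator summation: sum_t (lambda *
# t(P))^t e_seed, truncated at n_steps.
operator_influence <- function(W, seed_idx, lambda = 0.5, n_steps = 60) {
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  op <- lambda * t(P)
  u <- numeric(nrow(W)); u[seed_idx] <- 1
  total <- u
  for (t in seq_len(n_steps)) {
    u <- op %*% u
    total <- total + u
  }
  drop(total)
}
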