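# Shared fixtures: toy networks and weighted networks built in code.

mk_edges <- function(source, target, type) {
  data.frame(source = source, target = target, type = type,
             stringsAsFactors = FALSE)
}

# complete graph on the given node symbols, undirected type
mk_clique <- function(nodes, type = "undirected") {
  p <- t(combn(nodes, 2))
  mk_edges(p[, 1], p[, 2], type)
}

# two 5-cliques joined by a single bridge edge
mk_barbell <- function(k = 5) {
  a <- paste0("A", seq_len(k))
  b <- paste0("B", seq_len(k))
  signaling_network(rbind(mk_clique(a), mk_clique(b),
                          mk_edges("A1", "B1", "undirected")),
                    name = "barbell")
}

# wrap a signaling network + explicit weights into a weighted_network
mk_weighted <- function(net, weights, state = "toy", log_base = 10) {
  stopifnot(length(weights) == nrow(net$edges))
  structure(list(network = net, state = state, weights = weights,
                 log_base = log_base),
            class = "weighted_network")
}

# random connected typed weighted network: random spanning tree + extra
# edges, abundance-derived weights
random_typed_network <- function(n_nodes, n_extra = n_nodes,
                                 state = "rand") {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  src <- tgt <- character(0)
  for (v in 2:n_nodes) {           # random tree guarantees connectivity
    src <- c(src, nodes[sample.int(v - 1, 1)])
    tgt <- c(tgt, nodes[v])
  }
  have <- paste(pmin(src, tgt), pmax(src, tgt))
  tries <- 0
  while (length(src) < (n_nodes - 1) + n_extra && tries < 50 * n_extra) {
    pair <- sample(nodes, 2)
    key <- paste(min(pair), max(pair))
    tries <- tries + 1
    if (!key %in% have) {
      src <- c(src, pair[1]); tgt <- c(tgt, pair[2]); have <- c(have, key)
    }
  }
  type <- sample(c("activating", "inhibiting", "undirected"),
                 length(src), replace = TRUE,
                 prob = c(0.45, 0.15, 0.40))
  net <- signaling_network(mk_edges(src, tgt, type))
  ab <- setNames(pmax(rnorm(n_nodes, 8, 1.5), 0.6), nodes)
  compute_link_weights(net, ab, state = state)
}

# small synthetic configuration for fast unit tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_nodes = 60, n_edges = 150, n_samples = 8,
                   planted_module_size = 10, seed = seed, ...)
}
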