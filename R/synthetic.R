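# Synthetic study generator: typed network, three-state expression with a
# planted carcinoma-strengthened module and adenoma dispersion, gene sets,
# and ground truth for recovery tests.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the structure the analysis assumes: a sparse typed
#' network with edge-type proportions 2403/741/1915/30 (of 5089), log2
#' abundances centered near 8, three states sharing topology, a planted
#' connected module that strengthens in carcinoma (additive log2 shift
#' `carcinoma_effect`), and gene-level variance inflation in adenoma
#' (`adenoma_dispersion`, a multiplicative factor on the gene baselines'
#' deviation from the grand mean).
#'
#' @param n_nodes,n_edges network size (default 300 nodes, 1200 edges).
#' @param type_proportions length-4 numeric summing to 1 in the order
#'   activating, inhibiting, undirected, unknown.
#' @param n_samples samples per state (default 50).
#' @param baseline_mean,baseline_sd log2-scale gene baseline distribution
#'   (default 8, 1.5), truncated above 0.5.
#' @param planted_module_size size of the planted connected module
#'   (default 30).
#' @param carcinoma_effect additive log2 shift delta >= 0 on planted
#'   members in carcinoma (default 1).
#' @param adenoma_dispersion kappa >= 1 scaling gene-level deviations in
#'   adenoma (default 1.3).
#' @param sample_noise_sd per-sample log2 noise sd (default 0.5).
#' @param n_decoy_sets decoy gene sets emitted next to the planted one.
#' @param seed integer master seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 300, n_edges = 1200,
                             type_proportions = c(activating = 2403,
                                                  inhibiting = 741,
                                                  undirected = 1915,
                                                  unknown = 30) / 5089,
                             n_samples = 50,
                             baseline_mean = 8, baseline_sd = 1.5,
                             planted_module_size = 30,
                             carcinoma_effect = 1.0,
                             adenoma_dispersion = 1.3,
                             sample_noise_sd = 0.5,
                             n_decoy_sets = 5,
                             seed = 1) {
  stopifnot(n_nodes > 1, n_edges >= n_nodes - 1,
            length(type_proportions) == 4,
            abs(sum(type_proportions) - 1) < 1e-9,
            n_samples >= 1, planted_module_size >= 1,
            planted_module_size <= n_nodes,
            carcinoma_effect >= 0, adenoma_dispersion >= 1,
            sample_noise_sd > 0)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Largest-remainder apportionment
#'
#' Splits `n` items across categories in the given proportions: each
#' category gets the floor of its quota, and the leftover items go to the
#' categories with the largest fractional remainders (ties by category
#' order). Deterministic; counts always sum to `n`.
#'
#' @param n total count.
#' @param proportions numeric vector summing to 1.
#' @return Integer vector of counts (named like `proportions`).
#' @export
largest_remainder <- function(n, proportions) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  quota <- n * proportions
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    o <- order(-(quota - counts), seq_along(quota))
    counts[o[seq_len(left)]] <- counts[o[seq_len(left)]] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a connected typed network
#'
#' A preferential-attachment tree is grown and densified with uniformly
#' random extra edges (no self-loops, no duplicate pairs) up to `n_edges`;
#' edge types are allocated exactly by largest-remainder rounding of the
#' configured proportions and assigned to edges in random order.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [synthetic_config].
#' @return A [signaling_network] with node symbols `G001`, `G002`, ...
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_nodes
  max_edges <- n * (n - 1) / 2
  if (cfg$n_edges > max_edges) stop("more edges requested than node pairs")
  with_seed(cfg$seed, {
    deg <- integer(n)
    from <- integer(cfg$n_edges); to <- integer(cfg$n_edges)
    from[1] <- 1L; to[1] <- 2L
    deg[1:2] <- 1L
    for (v in 3:n) {
      t <- sample.int(v - 1, 1, prob = deg[seq_len(v - 1)])
      from[v - 1] <- t; to[v - 1] <- v
      deg[t] <- deg[t] + 1L; deg[v] <- deg[v] + 1L
    }
    k <- n - 1L
    seen <- new.env(hash = TRUE)
    for (i in seq_len(k))
      assign(paste(min(from[i], to[i]), max(from[i], to[i])), TRUE,
             envir = seen)
    while (k < cfg$n_edges) {
      pair <- sample.int(n, 2)
      key <- paste(min(pair), max(pair))
      if (!exists(key, envir = seen, inherits = FALSE)) {
        k <- k + 1L
        from[k] <- pair[1]; to[k] <- pair[2]
        assign(key, TRUE, envir = seen)
      }
    }
    counts <- largest_remainder(cfg$n_edges, cfg$type_proportions)
    types <- sample(rep(names(counts), counts))
    fmt <- paste0("G%0", nchar(as.character(n)), "d")
    signaling_network(
      data.frame(source = sprintf(fmt, from), target = sprintf(fmt, to),
                 type = types, stringsAsFactors = FALSE),
      name = "synthetic")
  })
}

#' Generate three-state expression matrices with planted effects
#'
#' Gene baselines are `Normal(baseline_mean, baseline_sd)` truncated above
#' 0.5. Normal-state samples add `Normal(0, sample_noise_sd)` noise;
#' adenoma uses gene means whose deviations from `baseline_mean` are
#' scaled by `adenoma_dispersion` (so per-state medians, and hence link-
#' weight spread, inherit the inflation); carcinoma adds
#' `carcinoma_effect` to the members of a planted connected module chosen
#' breadth-first from the highest-degree hub. Values are floored at 1e-3
#' to keep them positive.
#'
#' @param net a [generate_network()] network.
#' @param cfg the [synthetic_config] used to build it.
#' @return List with `normal`, `adenoma`, `carcinoma` ([expr_matrix]) and
#'   `truth` (planted members, per-state true gene means, hub).
#' @export
generate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "signaling_network"),
            inherits(cfg, "synthetic_config"))
  genes <- net$nodes
  n <- length(genes)
  with_seed(cfg$seed + 1L, {
    b <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    while (any(b <= 0.5))
      b[b <= 0.5] <- rnorm(sum(b <= 0.5), cfg$baseline_mean,
                           cfg$baseline_sd)
    names(b) <- genes

    g <- as_igraph(net, directed = FALSE)
    deg <- igraph::degree(g)
    hub <- sort(names(deg)[deg == max(deg)])[1]
    bfs_order <- names(igraph::bfs(g, root = hub, mode = "all")$order)
    planted <- sort(bfs_order[seq_len(cfg$planted_module_size)])

    mu <- list(
      normal    = b,
      adenoma   = pmax(cfg$baseline_mean +
                         cfg$adenoma_dispersion * (b - cfg$baseline_mean),
                       0.5),
      carcinoma = b + cfg$carcinoma_effect * (genes %in% planted))

    mats <- lapply(names(mu), function(st) {
      v <- matrix(rnorm(n * cfg$n_samples, mean = mu[[st]],
                        sd = cfg$sample_noise_sd),
                  nrow = n,
                  dimnames = list(genes,
                                  paste0(st, "_s",
                                         seq_len(cfg$n_samples))))
      v <- pmax(v, 1e-3)
      expr_matrix(v, state_label = st, series_id = "synthetic")
    })
    names(mats) <- names(mu)
    c(mats, list(truth = list(planted = planted, true_means = mu,
                              hub = hub)))
  })
}

#' Generate gene sets: the planted module plus size-matched decoys
#'
#' @param net a [signaling_network].
#' @param truth ground truth from [generate_expression()].
#' @param cfg the [synthetic_config].
#' @return A [gene_set_collection] with set `planted_module` and
#'   `decoy_1..n_decoy_sets` (sampled without replacement).
#' @export
generate_genesets <- function(net, truth, cfg) {
  with_seed(cfg$seed + 2L, {
    k <- length(truth$planted)
    sets <- c(list(planted_module = truth$planted),
              setNames(lapply(seq_len(cfg$n_decoy_sets), function(i)
                sort(sample(net$nodes, k))),
                paste0("decoy_", seq_len(cfg$n_decoy_sets))))
    gene_set_collection(sets,
                        setNames(c("planted carcinoma-strengthened module",
                                   rep("random decoy set",
                                       cfg$n_decoy_sets)),
                                 names(sets)))
  })
}

#' Generate a full synthetic study
#'
#' @param cfg a [synthetic_config].
#' @return List with `network`, `expression` (named list of
#'   [expr_matrix]), `gene_sets`, `truth` and `config`.
#' @export
generate_study <- function(cfg = synthetic_config()) {
  net <- generate_network(cfg)
  ex <- generate_expression(net, cfg)
  gs <- generate_genesets(net, ex$truth, cfg)
  list(network = net,
       expression = ex[c("normal", "adenoma", "carcinoma")],
       gene_sets = gs, truth = ex$truth, config = cfg)
}
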