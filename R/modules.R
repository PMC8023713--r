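# Overlapping-module detection via an influence-function community
# landscape: decaying weighted spreading from every node builds a height
# surface whose hills are modules; assignment strengths are the (row-
# normalized) influence zones of the hill cores.

# Symmetric node x node weight matrix of a weighted network (all link
# types treated as undirected for spreading; parallel links between a pair
# carry the same endpoint-product weight, so the duplicate collapses).
weight_matrix <- function(w) {
  stopifnot(inherits(w, "weighted_network"))
  nodes <- w$network$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- w$network$edges
  i <- match(e$source, nodes)
  j <- match(e$target, nodes)
  W[cbind(i, j)] <- pmax(W[cbind(i, j)], w$weights)
  W[cbind(j, i)] <- pmax(W[cbind(j, i)], w$weights)
  diag(W) <- 0
  W
}

# Influence matrix M[node, seed]: total influence of each seed's zone at
# each node, from synchronous decaying spreading. At every step each node
# passes lambda x (its current increment) to its neighbors in proportion
# to incident link weights; increments are accumulated until the largest
# per-seed total increment drops below eps.
influence_matrix <- function(W, lambda = 0.5, eps = 1e-6) {
  stopifnot(lambda > 0, lambda < 1, eps > 0)
  n <- nrow(W)
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  tP <- t(P)
  U <- diag(n)
  M <- diag(n)
  dimnames(M) <- dimnames(W)
  repeat {
    U <- lambda * (tP %*% U)
    M <- M + U
    if (max(colSums(U)) < eps) break
  }
  dimnames(M) <- dimnames(W)
  M
}

#' Influence zone of a single node
#'
#' Iterative weighted spreading from a seed: the seed starts with
#' influence 1 and at each step every node passes `lambda` times its
#' current increment to its neighbors proportionally to incident link
#' weights, until the total increment falls below `eps`. The result is the
#' seed's local influence zone over the network; an isolated seed keeps
#' all influence itself.
#'
#' @param w a [weighted_network].
#' @param seed_node node symbol.
#' @param lambda decay factor in (0, 1), default 0.5.
#' @param eps convergence tolerance on the total increment, default 1e-6.
#' @return Named numeric vector: node -> influence (>= 0), maximal at the
#'   seed.
#' @export
influence_zone <- function(w, seed_node, lambda = 0.5, eps = 1e-6) {
  W <- weight_matrix(w)
  if (!seed_node %in% rownames(W)) stop("seed node not in network: ",
                                        seed_node)
  stopifnot(lambda > 0, lambda < 1, eps > 0)
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  u <- setNames(numeric(nrow(W)), rownames(W))
  u[seed_node] <- 1
  total <- u
  repeat {
    u <- lambda * drop(crossprod(P, u))
    total <- total + u
    if (sum(u) < eps) break
  }
  total
}

# Proportional overlap of two (unnormalized) assignment vectors, computed
# outside the two core coordinates themselves: sum of coordinate-wise
# minima relative to the smaller vector mass. Two cores whose zones
# coincide away from the cores overlap at 1; disjoint zones at 0.
.zone_overlap <- function(v1, v2, excl) {
  keep <- setdiff(seq_along(v1), excl)
  if (length(keep) == 0) return(1)
  a <- v1[keep]; b <- v2[keep]
  denom <- min(sum(a), sum(b))
  if (denom <= 0) return(0)
  sum(pmin(a, b)) / denom
}

#' Detect overlapping modules via the community landscape
#'
#' The landscape height of a node is the summed influence it receives from
#' every node's influence zone. Module cores are local maxima of the
#' height (height >= all neighbors'); the assignment strength of a node to
#' a module is proportional to the core's influence at that node,
#' normalized per node so strengths sum to 1. Hills whose influence zones
#' proportionally overlap by more than `theta` (measured outside the core
#' nodes) are merged iteratively, highest overlap first, the surviving
#' core being the one of larger landscape height. Modules that end up with
#' no discrete member are dropped with a warning.
#'
#' @param w a [weighted_network] (connected, filtered).
#' @param lambda spreading decay, default 0.5.
#' @param eps spreading tolerance, default 1e-6.
#' @param theta merge threshold in (0, 1], default 0.9.
#' @return Object of class `module_landscape`: `assignment` (node x module
#'   matrix, rows summing to 1), `raw` (unnormalized zone matrix),
#'   `height`, `centrality` (per node), `modules` (data.frame id/core
#'   height/size) and `params`.
#' @export
detect_modules <- function(w, lambda = 0.5, eps = 1e-6, theta = 0.9) {
  stopifnot(theta > 0, theta <= 1)
  W <- weight_matrix(w)
  nodes <- rownames(W)
  M <- influence_matrix(W, lambda = lambda, eps = eps)
  h <- rowSums(M)
  centrality <- h
  adj <- W > 0
  is_core <- vapply(seq_along(nodes), function(i) {
    nb <- which(adj[i, ])
    length(nb) == 0 || h[i] >= max(h[nb])
  }, logical(1))
  cores <- nodes[is_core]
  zones <- M[, cores, drop = FALSE]          # columns: core influence zones
  member_cores <- setNames(as.list(cores), cores)  # constituent cores

  # iterative hill merging, highest overlap first; the overlap of two
  # hills is measured outside all of their constituent core nodes
  repeat {
    m <- ncol(zones)
    if (m < 2) break
    ids <- colnames(zones)
    best <- c(0, NA, NA)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      excl <- match(c(member_cores[[ids[a]]], member_cores[[ids[b]]]),
                    nodes)
      ov <- .zone_overlap(zones[, a], zones[, b], excl)
      if (ov > best[1]) best <- c(ov, a, b)
    }
    if (best[1] <= theta) break
    a <- best[2]; b <- best[3]
    ka <- ids[a]; kb <- ids[b]
    keep_id <- if (h[ka] > h[kb]) ka
               else if (h[kb] > h[ka]) kb
               else min(ka, kb)
    merged <- zones[, a] + zones[, b]
    merged_cores <- c(member_cores[[ka]], member_cores[[kb]])
    zones <- zones[, -c(a, b), drop = FALSE]
    zones <- cbind(zones, merged)
    colnames(zones)[ncol(zones)] <- keep_id
    member_cores[[setdiff(c(ka, kb), keep_id)]] <- NULL
    member_cores[[keep_id]] <- merged_cores
  }
  zones <- zones[, order(colnames(zones)), drop = FALSE]

  assignment <- .normalize_rows(zones, W, nodes)
  land <- structure(list(assignment = assignment, raw = zones,
                         height = h, centrality = centrality,
                         params = list(lambda = lambda, eps = eps,
                                       theta = theta),
                         state = w$state),
                    class = "module_landscape")
  # every module must own at least one discrete member
  da <- discrete_assignment(land)
  empty <- setdiff(colnames(assignment), unique(da))
  if (length(empty) > 0) {
    warning("dropping module(s) with no discrete member: ",
            paste(empty, collapse = ", "))
    keep <- setdiff(colnames(assignment), empty)
    land$raw <- land$raw[, keep, drop = FALSE]
    land$assignment <- .normalize_rows(land$raw, W, rownames(W))
  }
  land$modules <- data.frame(
    id = colnames(land$assignment),
    height = h[colnames(land$assignment)],
    size = as.integer(table(factor(discrete_assignment(land),
                                   levels = colnames(land$assignment)))),
    row.names = NULL)
  land
}

# Row-normalize zone columns into assignment strengths; nodes that receive
# (numerically) zero influence from every core fall back to the hop-nearest
# core, ties to the lexicographically smallest module id.
.normalize_rows <- function(zones, W, nodes) {
  rs <- rowSums(zones)
  assignment <- zones / ifelse(rs > 0, rs, 1)
  zero <- which(rs == 0)
  if (length(zero) > 0) {
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    hops <- igraph::distances(g, v = nodes[zero],
                              to = colnames(zones))
    for (k in seq_along(zero)) {
      j <- which(hops[k, ] == min(hops[k, ]))[1]
      assignment[zero[k], ] <- 0
      assignment[zero[k], j] <- 1
    }
  }
  assignment
}

#' @export
print.module_landscape <- function(x, ...) {
  cat(sprintf("module_landscape [%s]: %d nodes, %d modules (lambda=%g, theta=%g)\n",
              x$state %||% "?", nrow(x$assignment), ncol(x$assignment),
              x$params$lambda, x$params$theta))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Community centrality
#'
#' The sum of all local influence zones evaluated at a node — the whole
#' network's influence on that node, i.e. the height of the community
#' landscape there. Nodes with the largest community centrality within
#' their module are its main integrators and organizers.
#'
#' @param landscape a [detect_modules()] landscape (its stored centrality
#'   is returned if present).
#' @param w the underlying [weighted_network]; required if `landscape` is
#'   `NULL`.
#' @param ... spreading parameters passed to [influence_zone()] machinery.
#' @return Named numeric vector node -> centrality (>= 0).
#' @export
community_centrality <- function(landscape = NULL, w = NULL, ...) {
  if (!is.null(landscape)) {
    stopifnot(inherits(landscape, "module_landscape"))
    return(landscape$centrality)
  }
  stopifnot(inherits(w, "weighted_network"))
  W <- weight_matrix(w)
  rowSums(influence_matrix(W, ...))
}

#' Discrete module assignment
#'
#' Assigns each node to the module it mostly belongs to (row argmax of
#' assignment strengths); exact ties go to the lexicographically smallest
#' module id.
#'
#' @param landscape a [module_landscape].
#' @return Named character vector node -> module id.
#' @export
discrete_assignment <- function(landscape) {
  stopifnot(inherits(landscape, "module_landscape"))
  A <- landscape$assignment
  ids <- colnames(A)[order(colnames(A))]
  A <- A[, ids, drop = FALSE]
  out <- ids[apply(A, 1, which.max)]  # which.max takes first = smallest id
  setNames(out, rownames(A))
}

#' Name modules after their organizer node
#'
#' A module is named for the node with the largest community centrality
#' among its discrete members (ties: lexicographically smallest symbol).
#'
#' @param landscape a [module_landscape].
#' @return Named character vector module id -> organizer symbol.
#' @export
name_modules <- function(landscape) {
  stopifnot(inherits(landscape, "module_landscape"))
  da <- discrete_assignment(landscape)
  cent <- landscape$centrality
  ids <- colnames(landscape$assignment)
  nm <- vapply(ids, function(m) {
    members <- sort(names(da)[da == m])
    if (length(members) == 0) return(NA_character_)
    members[which.max(cent[members])]
  }, character(1))
  if (anyNA(nm)) {
    warning("dropping unnamed module(s) with empty discrete membership")
    nm <- nm[!is.na(nm)]
  }
  nm
}

#' Modular overlap and effective degree
#'
#' `modular_overlap` is the effective number of modules a node belongs to:
#' the exponential of the Shannon entropy of its assignment row (1 for a
#' node fully in one module, k for a node spread evenly over k).
#' `effective_degree` is the node's weighted degree (sum of incident link
#' weights).
#'
#' @param landscape a [module_landscape].
#' @param w the underlying [weighted_network].
#' @return data.frame with columns node, modular_overlap, effective_degree.
#' @export
overlap_metrics <- function(landscape, w) {
  stopifnot(inherits(landscape, "module_landscape"),
            inherits(w, "weighted_network"))
  A <- landscape$assignment
  ent <- apply(A, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  W <- weight_matrix(w)
  data.frame(node = rownames(A),
             modular_overlap = exp(ent),
             effective_degree = rowSums(W)[rownames(A)],
             row.names = NULL)
}

#' Match modules across two states
#'
#' Each module of landscape `a` is mapped to the module of `b` receiving
#' the plurality of its discrete members (ties: lexicographically smallest
#' target id), with the Jaccard similarity of the two discrete member
#' sets. Pairs are annotated `"merge"` when two or more modules of `a` map
#' to one module of `b`, `"split"` when the reverse mapping sends two or
#' more modules of `b` to the same module of `a`.
#'
#' @param a,b [module_landscape]s over the same node set.
#' @return data.frame: module_a, module_b, jaccard, annotation.
#' @export
match_modules <- function(a, b) {
  stopifnot(inherits(a, "module_landscape"),
            inherits(b, "module_landscape"))
  da <- discrete_assignment(a)
  db <- discrete_assignment(b)
  shared <- intersect(names(da), names(db))
  if (length(shared) == 0) stop("landscapes share no nodes")
  da <- da[shared]; db <- db[shared]
  map_to <- function(src, dst) {
    mods <- sort(unique(src))
    vapply(mods, function(m) {
      members <- names(src)[src == m]
      tab <- table(dst[members])
      winners <- names(tab)[tab == max(tab)]
      sort(winners)[1]
    }, character(1))
  }
  fwd <- map_to(da, db)
  bwd <- map_to(db, da)
  jac <- vapply(names(fwd), function(m) {
    ma <- names(da)[da == m]
    mb <- names(db)[db == fwd[[m]]]
    length(intersect(ma, mb)) / length(union(ma, mb))
  }, numeric(1))
  merge_targets <- names(table(fwd))[table(fwd) >= 2]
  ann <- vapply(names(fwd), function(m) {
    tags <- character(0)
    if (fwd[[m]] %in% merge_targets) tags <- c(tags, "merge")
    back <- names(bwd)[bwd == m]
    if (length(back) >= 2) tags <- c(tags, "split")
    if (length(tags) == 0) "stable" else paste(tags, collapse = "+")
  }, character(1))
  data.frame(module_a = names(fwd), module_b = unname(fwd),
             jaccard = unname(jac), annotation = unname(ann),
             row.names = NULL)
}
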