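# Weighted diameter and average path length under three directivity
# conventions.

#' Build a distance graph from a weighted state network
#'
#' Link weights are probability-like (higher = more likely interaction), so
#' they are mapped to non-negative path lengths before shortest-path
#' analysis. The negative natural logarithm is applied to the unlogged
#' abundance product `W = base^LW`, normalized by the maximum
#' (`"neglog-maxnorm"`, default: `d = ln(W_max / W)`) or the sum
#' (`"neglog-sumnorm"`) of the state network's products — equivalently,
#' with max-normalization, `d = ln(base) * (LW_max - LW)`. The most
#' likely link then has distance 0, Dijkstra's shortest path is the most
#' likely transition path, and rescaling all abundances by a common
#' factor leaves every distance unchanged. The reference is always taken
#' over the *full* state network so the three directivity views share one
#' distance scale.
#'
#' @param w a [weighted_network].
#'
#' Conventions: `"undirected"` drops all directivity; `"directed"` keeps
#' only activating/inhibiting links as arcs; `"mixed"` keeps directed arcs
#' and replaces each undirected link by two opposite arcs of equal
#' distance. The undirected view is restricted to its largest connected
#' component, the directed and mixed views to their largest strongly
#' connected component, so all pairs are reachable. Parallel arcs between
#' a node pair keep the minimum distance.
#'
#' @param convention `"undirected"`, `"directed"` or `"mixed"`.
#' @param distance_map `"neglog-maxnorm"` (default) or `"neglog-sumnorm"`.
#' @return Object of class `distance_graph`: an igraph graph with edge
#'   attribute `dist`, plus the convention and reference weight.
#' @export
build_view <- function(w,
                       convention = c("undirected", "directed", "mixed"),
                       distance_map = c("neglog-maxnorm",
                                        "neglog-sumnorm")) {
  stopifnot(inherits(w, "weighted_network"))
  convention <- match.arg(convention)
  distance_map <- match.arg(distance_map)
  raw <- w$log_base^w$weights   # back to the abundance-product scale
  w_ref <- if (distance_map == "neglog-maxnorm") max(raw) else sum(raw)
  e <- w$network$edges
  d <- log(w_ref / raw)
  if (any(e$type == "unknown")) {
    warning("dropping unknown-type links from the distance graph")
    d <- d[e$type != "unknown"]
    e <- e[e$type != "unknown", , drop = FALSE]
  }
  directed_rows <- e$type %in% c("activating", "inhibiting")
  if (convention == "undirected") {
    arcs <- data.frame(from = e$source, to = e$target, dist = d)
  } else if (convention == "directed") {
    arcs <- data.frame(from = e$source[directed_rows],
                       to = e$target[directed_rows],
                       dist = d[directed_rows])
  } else {
    u <- !directed_rows
    arcs <- rbind(
      data.frame(from = e$source[directed_rows],
                 to = e$target[directed_rows], dist = d[directed_rows]),
      data.frame(from = e$source[u], to = e$target[u], dist = d[u]),
      data.frame(from = e$target[u], to = e$source[u], dist = d[u]))
  }
  if (nrow(arcs) == 0)
    stop(sprintf("no links contribute arcs under the '%s' convention",
                 convention))
  # parallel arcs: keep the minimum distance
  key <- if (convention == "undirected") {
    paste(pmin(arcs$from, arcs$to), pmax(arcs$from, arcs$to))
  } else paste(arcs$from, arcs$to)
  o <- order(key, arcs$dist)
  arcs <- arcs[o, , drop = FALSE]
  key <- key[o]
  arcs <- arcs[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    arcs, directed = convention != "undirected")
  comp <- igraph::components(
    g, mode = if (convention == "undirected") "weak" else "strong")
  giant <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, giant)
  structure(list(graph = g, convention = convention,
                 distance_map = distance_map, w_ref = w_ref,
                 state = w$state),
            class = "distance_graph")
}

.distance_matrix <- function(g) {
  igraph::distances(g$graph, mode = "out",
                    weights = igraph::E(g$graph)$dist,
                    algorithm = "dijkstra")
}

#' Weighted network diameter
#'
#' The longest of all-pairs Dijkstra shortest paths on a distance graph,
#' with the node pair and path realizing it. The diametral pair is made
#' deterministic by choosing the lexicographically smallest (source,
#' target) pair among ties.
#'
#' @param g a [build_view()] distance graph.
#' @return List with `diameter`, `endpoints` (length-2 character),
#'   `path` (node symbols along the diameter) and `n_reachable_pairs`.
#' @export
weighted_diameter <- function(g) {
  stopifnot(inherits(g, "distance_graph"))
  D <- .distance_matrix(g)
  diag(D) <- NA
  if (any(!is.finite(D) & !is.na(D)))
    stop("distance graph is not connected in the relevant sense")
  dm <- max(D, na.rm = TRUE)
  hits <- which(D == dm, arr.ind = TRUE)
  nm <- rownames(D)
  pairs <- data.frame(from = nm[hits[, 1]], to = nm[hits[, 2]])
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  ep <- c(pairs$from[1], pairs$to[1])
  sp <- igraph::shortest_paths(g$graph, from = ep[1], to = ep[2],
                               mode = "out",
                               weights = igraph::E(g$graph)$dist)
  list(diameter = dm, endpoints = ep,
       path = names(sp$vpath[[1]]),
       n_reachable_pairs = sum(!is.na(D)))
}

#' Average shortest-path length
#'
#' Mean Dijkstra shortest-path distance over all ordered reachable pairs
#' (i != j); on the undirected view this equals the unordered-pair mean.
#'
#' @param g a [build_view()] distance graph.
#' @return Numeric scalar.
#' @export
average_path_length <- function(g) {
  stopifnot(inherits(g, "distance_graph"))
  D <- .distance_matrix(g)
  diag(D) <- NA
  mean(D, na.rm = TRUE)
}

#' Diameter report for one state under all three conventions
#'
#' @param w a [weighted_network].
#' @param conventions subset of the three directivity conventions.
#' @param distance_map passed to [build_view()].
#' @return data.frame with one row per convention: diameter, average path
#'   length, diametral endpoints, component size, reachable pairs.
#' @export
diameter_report <- function(w, conventions = c("undirected", "directed",
                                               "mixed"),
                            distance_map = "neglog-maxnorm") {
  rows <- lapply(conventions, function(cv) {
    g <- build_view(w, convention = cv, distance_map = distance_map)
    wd <- weighted_diameter(g)
    data.frame(state = w$state, convention = cv,
               diameter = wd$diameter,
               avg_path_length = average_path_length(g),
               from = wd$endpoints[1], to = wd$endpoints[2],
               n_nodes = igraph::vcount(g$graph),
               n_reachable_pairs = wd$n_reachable_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diameter grid across states
#'
#' @param weighted_list named list of [weighted_network]s (state -> network).
#' @param ... passed to [diameter_report()].
#' @return data.frame, states x conventions (long form).
#' @export
diameter_grid <- function(weighted_list, ...) {
  do.call(rbind, lapply(weighted_list, diameter_report, ...))
}
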