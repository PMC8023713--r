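# Per-state link weights, distribution statistics, paired tests,
# extreme-link strata.

#' Compute per-state link weights
#'
#' The weight of a link is the logarithm of the product of its endpoint
#' abundances, `LW(i,j) = log_b(a_i * a_j)` — a proxy for the probability
#' of the signaling interaction. With log2-scale abundances near 8 and the
#' default base 10 this puts weights near `log10(64) ~ 1.8`, the scale on
#' which the weak/medium/strong bins at 2 and 2.7 are defined.
#'
#' @param net a filtered [signaling_network].
#' @param abundance named numeric vector gene -> abundance for one state
#'   (or an [abundance_table] column).
#' @param log_base logarithm base, default 10.
#' @param state state label stored on the result.
#' @return Object of class `weighted_network`: the network plus a numeric
#'   `weights` vector aligned with `net$edges` rows.
#' @export
compute_link_weights <- function(net, abundance, log_base = 10,
                                 state = "state") {
  stopifnot(inherits(net, "signaling_network"), is.numeric(abundance),
            !is.null(names(abundance)))
  missing_genes <- setdiff(net$nodes, names(abundance))
  if (length(missing_genes) > 0)
    stop("no abundance for gene(s): ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  a <- abundance[net$edges$source] * abundance[net$edges$target]
  if (any(a <= 0)) stop("non-positive abundance product")
  w <- log(a, base = log_base)
  structure(list(network = net, state = state,
                 weights = unname(w), log_base = log_base),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network [%s]: %d edges, weight range %.3f..%.3f\n",
              x$state, length(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Summarize a state's link-weight distribution
#'
#' Location/spread statistics plus the fractions of weak, medium and strong
#' links (bin boundaries default to 2 and 2.7: weak `< 2`, medium
#' `[2, 2.7]`, strong `> 2.7`) and the cumulative distribution curve.
#' Quartiles use linear interpolation between order statistics.
#'
#' @param w a [weighted_network].
#' @param boundaries two increasing bin edges, default `c(2, 2.7)`.
#' @return Object of class `weight_summary`.
#' @export
summarize_weights <- function(w, boundaries = c(2, 2.7)) {
  stopifnot(inherits(w, "weighted_network"),
            length(boundaries) == 2, boundaries[1] < boundaries[2])
  x <- w$weights
  if (length(x) < 2) stop("need >= 2 edges to summarize")
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bins <- c(weak   = mean(x < boundaries[1]),
            medium = mean(x >= boundaries[1] & x <= boundaries[2]),
            strong = mean(x > boundaries[2]))
  xs <- sort(x)
  structure(list(state = w$state, n = length(x),
                 median = qs[2], mean = mean(x), sd = sd(x),
                 q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1],
                 min = min(x), max = max(x),
                 bin_fractions = bins, boundaries = boundaries,
                 cumulative = data.frame(weight = xs,
                                         cumulative = seq_along(xs) /
                                           length(xs))),
            class = "weight_summary")
}

#' @export
print.weight_summary <- function(x, ...) {
  cat(sprintf(paste0("weight_summary [%s]: n=%d median=%.4f sd=%.4f ",
                     "q1=%.4f q3=%.4f min=%.4f max=%.4f\n"),
              x$state, x$n, x$median, x$sd, x$q1, x$q3, x$min, x$max))
  cat(sprintf("  bins (<%.4g / [%.4g,%.4g] / >%.4g): %.3f / %.3f / %.3f\n",
              x$boundaries[1], x$boundaries[1], x$boundaries[2],
              x$boundaries[2], x$bin_fractions[1], x$bin_fractions[2],
              x$bin_fractions[3]))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic under ties: counts of
# sign assignments per value of 2*W (doubled mid-ranks are integers).
.signed_rank_counts <- function(s2) {
  total <- sum(s2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (si in s2) {
    shifted <- c(numeric(si), counts[seq_len(total + 1 - si)])
    counts <- counts + shifted
  }
  counts  # counts[k+1] = number of assignments with 2*W == k
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test on per-edge (or per-gene) values of
#' two states. Zero differences are removed; for `n <= 25` remaining pairs
#' the exact permutation distribution is used (valid under tied ranks,
#' via doubled mid-ranks), above that a normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric vectors aligned on the same edges/genes (>= 2 pairs).
#' @return List with `statistic` (W, sum of positive-difference ranks),
#'   `p.value` (two-sided), `n` (pairs after zero removal) and `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must be aligned (equal length)")
  if (length(x) < 2) stop("need >= 2 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate pairing: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    s2 <- as.integer(round(2 * r))
    counts <- .signed_rank_counts(s2)
    tot <- 2^n
    k <- as.integer(round(2 * W))
    p_lo <- sum(counts[seq_len(k + 1)]) / tot
    p_hi <- sum(counts[(k + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = W, p.value = p, n = n, method = method)
}

#' Extract the strongest and weakest link strata
#'
#' Picks the top/bottom `decile` fraction of links by weight and, within
#' those, the top/bottom `percentile` fraction. Stratum sizes are
#' `floor(fraction * E)`; ties at a boundary are broken deterministically
#' by (weight, source, target) lexicographic order.
#'
#' @param w a [weighted_network].
#' @param decile outer fraction, default 0.10.
#' @param percentile inner fraction, default 0.01.
#' @return Object of class `extreme_links`: the weighted edge table plus
#'   integer index vectors `top_decile`, `top_percentile`, `bottom_decile`,
#'   `bottom_percentile` into that table.
#' @export
extreme_links <- function(w, decile = 0.10, percentile = 0.01) {
  stopifnot(inherits(w, "weighted_network"))
  if (decile <= 0 || decile >= 0.5 || percentile <= 0 || percentile >= 0.5)
    stop("strata fractions must lie in (0, 0.5)")
  if (percentile > decile) stop("percentile fraction exceeds decile fraction")
  e <- w$network$edges
  e$weight <- w$weights
  E <- nrow(e)
  n_dec <- floor(decile * E)
  n_pct <- floor(percentile * E)
  if (n_dec < 1) stop("too few edges for the requested decile fraction")
  ord_hi <- order(-e$weight, e$source, e$target)
  ord_lo <- order(e$weight, e$source, e$target)
  structure(list(state = w$state, edges = e,
                 top_decile = ord_hi[seq_len(n_dec)],
                 top_percentile = ord_hi[seq_len(n_pct)],
                 bottom_decile = ord_lo[seq_len(n_dec)],
                 bottom_percentile = ord_lo[seq_len(n_pct)],
                 decile = decile, percentile = percentile),
            class = "extreme_links")
}

#' Per-module representation in the extreme strata
#'
#' An edge belongs to a module when *both* endpoints are discretely
#' assigned to it (edges spanning two modules count for neither). The
#' representation ratio of a module in a stratum is the fraction of the
#' module's edges that fall in that stratum.
#'
#' @param report an [extreme_links] report.
#' @param assignment named character vector node -> module (discrete
#'   assignment) covering all network nodes.
#' @return data.frame: one row per module with its internal edge count and
#'   the four stratum ratios.
#' @export
module_representation <- function(report, assignment) {
  stopifnot(inherits(report, "extreme_links"), !is.null(names(assignment)))
  e <- report$edges
  nodes <- unique(c(e$source, e$target))
  if (!all(nodes %in% names(assignment)))
    stop("assignment does not cover all network nodes")
  ms <- assignment[e$source]
  mt <- assignment[e$target]
  internal <- ms == mt
  edge_mod <- ifelse(internal, ms, NA_character_)
  mods <- sort(unique(assignment))
  strata <- c("top_decile", "top_percentile",
              "bottom_decile", "bottom_percentile")
  out <- data.frame(module = mods,
                    n_edges = vapply(mods, function(m)
                      sum(edge_mod == m, na.rm = TRUE), integer(1)))
  for (s in strata) {
    idx <- report[[s]]
    out[[s]] <- vapply(mods, function(m) {
      ne <- sum(edge_mod == m, na.rm = TRUE)
      if (ne == 0) return(0)
      sum(edge_mod[idx] == m, na.rm = TRUE) / ne
    }, numeric(1))
  }
  if (any(out$n_edges == 0))
    warning("module(s) with no internal edge: ",
            paste(out$module[out$n_edges == 0], collapse = ", "))
  rownames(out) <- NULL
  out
}
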