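# Gene-set-level statistics: per-state medians, normality screening,
# paired Wilcoxon comparisons, weighted-degree ratios, extreme-link counts.

#' Per-state median abundance of a gene set
#'
#' Members are restricted to network nodes before the median is taken.
#'
#' @param members character vector of gene symbols (one gene set).
#' @param ab an [abundance_table] (genes x states).
#' @param net the filtered [signaling_network].
#' @return List with `n_in_geneset`, `n_in_network` and `medians` (named
#'   per-state vector; all `NA` when no member is in the network).
#' @export
pathway_medians <- function(members, ab, net) {
  stopifnot(length(members) > 0, inherits(net, "signaling_network"))
  in_net <- intersect(members, intersect(net$nodes, rownames(ab)))
  med <- if (length(in_net) == 0) {
    setNames(rep(NA_real_, ncol(ab)), colnames(ab))
  } else {
    apply(ab[in_net, , drop = FALSE], 2, median)
  }
  list(n_in_geneset = length(unique(members)),
       n_in_network = length(in_net),
       medians = med)
}

#' Pairwise paired Wilcoxon tests for a gene set, with a normality screen
#'
#' For every pair of states, the per-gene abundances of the in-network
#' members are compared with the paired signed-rank test of
#' [paired_wilcoxon()]. A Shapiro-Wilk p-value per state is reported for
#' transparency (the rank test is used regardless). Gene sets with fewer
#' than 5 in-network members, or degenerate all-zero differences, yield
#' `NA` p-values.
#'
#' @inheritParams pathway_medians
#' @return List with `wilcoxon` (data.frame state_a, state_b, p) and
#'   `shapiro` (named per-state p-values, `NA` if not computable).
#' @export
pathway_tests <- function(members, ab, net) {
  in_net <- intersect(members, intersect(net$nodes, rownames(ab)))
  states <- colnames(ab)
  shapiro <- setNames(rep(NA_real_, length(states)), states)
  if (length(in_net) >= 3 && length(in_net) <= 5000) {
    for (s in states) {
      v <- ab[in_net, s]
      if (length(unique(v)) > 1)
        shapiro[s] <- stats::shapiro.test(v)$p.value
    }
  }
  pairs <- utils::combn(states, 2)
  p <- apply(pairs, 2, function(st) {
    if (length(in_net) < 5) return(NA_real_)
    res <- tryCatch(paired_wilcoxon(ab[in_net, st[1]], ab[in_net, st[2]]),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$p.value
  })
  list(wilcoxon = data.frame(state_a = pairs[1, ], state_b = pairs[2, ],
                             p = p, row.names = NULL),
       shapiro = shapiro)
}

#' Weighted-degree ratio of a gene set
#'
#' Weighted degree = sum of incident link weights. Reports the median over
#' in-network members, the network-wide median, and their ratio.
#'
#' @param members gene symbols.
#' @param w a [weighted_network].
#' @return List with `member_median`, `network_median`, `ratio`,
#'   `n_members`.
#' @export
pathway_weighted_degree <- function(members, w) {
  stopifnot(inherits(w, "weighted_network"))
  W <- weight_matrix(w)
  deg <- rowSums(W)
  in_net <- intersect(members, names(deg))
  if (length(in_net) == 0)
    return(list(member_median = NA_real_, network_median = median(deg),
                ratio = NA_real_, n_members = 0L))
  mm <- median(deg[in_net])
  nm <- median(deg)
  list(member_median = mm, network_median = nm, ratio = mm / nm,
       n_members = length(in_net))
}

#' Count gene-set-associated links in the extreme strata
#'
#' A link is pathway-associated when at least one endpoint (mode
#' `"any"`, default) or both endpoints (mode `"both"`) belong to the set.
#'
#' @param members gene symbols.
#' @param report an [extreme_links] report.
#' @param mode `"any"` or `"both"`.
#' @return Named integer vector: `top` and `bottom` counts over the
#'   top/bottom deciles.
#' @export
pathway_extreme_counts <- function(members, report, mode = c("any", "both")) {
  stopifnot(inherits(report, "extreme_links"))
  mode <- match.arg(mode)
  e <- report$edges
  assoc <- if (mode == "any") {
    e$source %in% members | e$target %in% members
  } else {
    e$source %in% members & e$target %in% members
  }
  c(top = sum(assoc[report$top_decile]),
    bottom = sum(assoc[report$bottom_decile]))
}

#' Pathway summary table across states
#'
#' One row per gene set: membership counts, per-state median abundances,
#' pairwise paired-Wilcoxon p-values, per-state weighted-degree ratios and
#' extreme-link counts.
#'
#' @param gs a [gene_set_collection].
#' @param ab an [abundance_table].
#' @param net the filtered [signaling_network].
#' @param weighted named list state -> [weighted_network].
#' @param extremes named list state -> [extreme_links].
#' @param mode endpoint rule for [pathway_extreme_counts()].
#' @return data.frame, one row per gene set.
#' @export
pathway_report <- function(gs, ab, net, weighted, extremes,
                           mode = "any") {
  stopifnot(inherits(gs, "gene_set_collection"))
  states <- colnames(ab)
  rows <- lapply(names(gs$sets), function(nm) {
    members <- gs$sets[[nm]]
    pm <- pathway_medians(members, ab, net)
    row <- data.frame(pathway = nm,
                      n_in_geneset = pm$n_in_geneset,
                      n_in_network = pm$n_in_network)
    for (s in states)
      row[[paste0("median_", s)]] <- pm$medians[[s]]
    pt <- pathway_tests(members, ab, net)
    for (k in seq_len(nrow(pt$wilcoxon)))
      row[[paste0("p_", pt$wilcoxon$state_a[k], "_",
                  pt$wilcoxon$state_b[k])]] <- pt$wilcoxon$p[k]
    for (s in states) {
      wd <- pathway_weighted_degree(members, weighted[[s]])
      row[[paste0("wdeg_ratio_", s)]] <- wd$ratio
      xc <- pathway_extreme_counts(members, extremes[[s]], mode = mode)
      row[[paste0("top10_", s)]] <- xc[["top"]]
      row[[paste0("bottom10_", s)]] <- xc[["bottom"]]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
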