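# End-to-end orchestration: simulate-or-load -> abundances -> weights ->
# diameters -> modules -> extremes -> pathways -> noise robustness.

#' Run configuration
#'
#' @param sim a [synthetic_config] (synthetic mode), or `NULL` for load
#'   mode.
#' @param network_path,expression_paths,gmt_path load-mode inputs:
#'   an edge-list file, a named list (state -> character vector of
#'   expression TSVs) and a GMT file.
#' @param log_base link-weight logarithm base.
#' @param distance_map distance mapping for [build_view()].
#' @param lambda,eps,theta module-landscape parameters.
#' @param decile,percentile extreme-link strata fractions.
#' @param noise_fraction multiplicative noise fraction for robustness.
#' @param n_noise_replicates robustness replicates (0 disables).
#' @param seed master seed; stages derive their own seeds by fixed offsets.
#' @param outdir output directory for TSV/JSON reports, or `NULL`.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = synthetic_config(),
                       network_path = NULL, expression_paths = NULL,
                       gmt_path = NULL,
                       log_base = 10, distance_map = "neglog-maxnorm",
                       lambda = 0.5, eps = 1e-6, theta = 0.9,
                       decile = 0.10, percentile = 0.01,
                       noise_fraction = 0.05, n_noise_replicates = 0,
                       seed = 1, outdir = NULL) {
  cfg <- as.list(environment())
  if (is.null(sim)) {
    for (p in c(network_path, unlist(expression_paths), gmt_path))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  class(cfg) <- "run_config"
  cfg
}

# abundance table from a named list of lists of expr_matrix
.abundances_from_expression <- function(expression) {
  by_state <- lapply(expression, function(mats) {
    if (inherits(mats, "expr_matrix")) mats <- list(mats)
    median_aggregate(lapply(mats, quantile_normalize))
  })
  abundance_table(by_state)
}

# weights/summaries/extremes/diameters for one abundance table
.state_layer <- function(net, ab, cfg) {
  states <- colnames(ab)
  weighted <- lapply(states, function(s)
    compute_link_weights(net, ab[, s], log_base = cfg$log_base, state = s))
  names(weighted) <- states
  list(weighted = weighted,
       summaries = lapply(weighted, summarize_weights),
       extremes = lapply(weighted, extreme_links,
                         decile = cfg$decile,
                         percentile = cfg$percentile),
       diameters = diameter_grid(weighted,
                                 distance_map = cfg$distance_map))
}

#' Run the complete analysis
#'
#' Stages: (1) simulate or load the study inputs; (2) filter the network
#' to measured genes, known link types and the giant component;
#' (3) quantile-normalize and median-aggregate expression into per-state
#' abundances; (4) per-state link weights, distribution summaries and
#' pairwise paired Wilcoxon tests; (5) weighted diameters and average path
#' lengths under the three directivity conventions; (6) module landscapes,
#' cross-state module matches and module naming; (7) extreme-link strata
#' and per-module representation; (8) pathway table; (9) optional noise
#' robustness. Writes TSV/JSON reports when `cfg$outdir` is set.
#'
#' @param cfg a [run_config].
#' @return A `pipeline_report` list with all stage outputs.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  study <- stage("input", {
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      generate_study(sim)
    } else {
      list(network = read_network(cfg$network_path),
           expression = lapply(setNames(nm = names(cfg$expression_paths)),
                               function(s)
                                 lapply(cfg$expression_paths[[s]],
                                        read_expression, state_label = s)),
           gene_sets = if (!is.null(cfg$gmt_path)) read_gmt(cfg$gmt_path),
           truth = NULL)
    }
  })

  ab <- stage("abundance", .abundances_from_expression(study$expression))
  net <- stage("filter", filter_network(study$network, rownames(ab)))
  layer <- stage("weights", .state_layer(net, ab, cfg))
  states <- colnames(ab)

  wilcoxon <- stage("wilcoxon", {
    pairs <- utils::combn(states, 2)
    do.call(rbind, apply(pairs, 2, function(st) {
      res <- paired_wilcoxon(layer$weighted[[st[1]]]$weights,
                             layer$weighted[[st[2]]]$weights)
      data.frame(state_a = st[1], state_b = st[2],
                 W = res$statistic, p = res$p.value, n = res$n)
    }, simplify = FALSE))
  })

  landscapes <- stage("modules", lapply(layer$weighted, detect_modules,
                                        lambda = cfg$lambda, eps = cfg$eps,
                                        theta = cfg$theta))
  matches <- stage("module_matching", {
    out <- list()
    for (k in seq_len(length(states) - 1)) {
      key <- paste(states[k], states[k + 1], sep = "_to_")
      out[[key]] <- match_modules(landscapes[[states[k]]],
                                  landscapes[[states[k + 1]]])
    }
    out
  })
  representation <- stage("representation", {
    lapply(setNames(nm = states), function(s)
      module_representation(layer$extremes[[s]],
                            discrete_assignment(landscapes[[s]])))
  })

  pathways <- stage("pathways", {
    if (is.null(study$gene_sets)) NULL
    else pathway_report(study$gene_sets, ab, net, layer$weighted,
                        layer$extremes)
  })

  noise <- if (cfg$n_noise_replicates >= 1) {
    stage("noise_robustness",
          noise_robustness(net, ab, cfg,
                           n_replicates = cfg$n_noise_replicates,
                           baseline = layer))
  } else NULL

  report <- list(config = cfg, network = net, abundances = ab,
                 weights = layer$weighted, summaries = layer$summaries,
                 wilcoxon = wilcoxon, diameters = layer$diameters,
                 landscapes = landscapes, matches = matches,
                 extremes = layer$extremes,
                 representation = representation,
                 pathways = pathways, noise = noise,
                 truth = study$truth)
  class(report) <- "pipeline_report"
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

# states ordered by diameter, one convention
.diameter_order <- function(grid, convention) {
  g <- grid[grid$convention == convention, ]
  paste(g$state[order(g$diameter)], collapse = "<")
}

#' Noise-robustness analysis
#'
#' Re-runs the weight-dependent stages under independent +/- `fraction`
#' multiplicative abundance perturbations (a zero fraction re-runs the
#' baseline unperturbed) and reports the fraction of
#' replicates preserving the unperturbed baseline's (i) per-convention
#' diameter ordering of the states, (ii) pairwise Wilcoxon significance
#' calls (p < 1e-4), and (iii) cross-state module-match annotations.
#'
#' @param net filtered [signaling_network].
#' @param ab baseline [abundance_table].
#' @param cfg a [run_config].
#' @param n_replicates number of perturbed replicates (>= 1).
#' @param baseline optional precomputed `.state_layer()` output.
#' @return List with `stability` (named fractions), per-replicate
#'   `diameter_grids`, the baseline grid, and the replicate seeds.
#' @export
noise_robustness <- function(net, ab, cfg, n_replicates = 5,
                             baseline = NULL) {
  stopifnot(n_replicates >= 1)
  if (is.null(baseline)) baseline <- .state_layer(net, ab, cfg)
  states <- colnames(ab)
  conventions <- unique(baseline$diameters$convention)
  base_order <- vapply(conventions, .diameter_order,
                       character(1), grid = baseline$diameters)
  base_wil <- vapply(seq_len(length(states) - 1), function(k) {
    res <- paired_wilcoxon(baseline$weighted[[states[k]]]$weights,
                           baseline$weighted[[states[k + 1]]]$weights)
    res$p.value < 1e-4
  }, logical(1))
  base_land <- lapply(baseline$weighted, detect_modules,
                      lambda = cfg$lambda, eps = cfg$eps, theta = cfg$theta)
  base_match <- lapply(seq_len(length(states) - 1), function(k)
    match_modules(base_land[[states[k]]], base_land[[states[k + 1]]]))

  rep_seeds <- cfg$seed + 1000L + seq_len(n_replicates)
  grids <- vector("list", n_replicates)
  diam_ok <- match_ok <- wilcox_ok <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    ab_r <- if (cfg$noise_fraction == 0) ab
            else perturb_noise(ab, fraction = cfg$noise_fraction,
                               seed = rep_seeds[r])
    layer_r <- .state_layer(net, ab_r, cfg)
    grids[[r]] <- layer_r$diameters
    ord <- vapply(conventions, .diameter_order, character(1),
                  grid = layer_r$diameters)
    diam_ok[r] <- all(ord == base_order)
    wil <- vapply(seq_len(length(states) - 1), function(k) {
      res <- paired_wilcoxon(layer_r$weighted[[states[k]]]$weights,
                             layer_r$weighted[[states[k + 1]]]$weights)
      res$p.value < 1e-4
    }, logical(1))
    wilcox_ok[r] <- all(wil == base_wil)
    land_r <- lapply(layer_r$weighted, detect_modules, lambda = cfg$lambda,
                     eps = cfg$eps, theta = cfg$theta)
    mt <- lapply(seq_len(length(states) - 1), function(k)
      match_modules(land_r[[states[k]]], land_r[[states[k + 1]]]))
    match_ok[r] <- all(vapply(seq_along(mt), function(k) {
      a <- base_match[[k]]; b <- mt[[k]]
      identical(a$annotation[order(a$module_a)],
                b$annotation[order(b$module_a)]) &&
        identical(sort(a$module_a), sort(b$module_a))
    }, logical(1)))
  }
  list(stability = c(diameter_ordering = mean(diam_ok),
                     wilcoxon_significance = mean(wilcox_ok),
                     module_matches = mean(match_ok)),
       baseline_grid = baseline$diameters,
       diameter_grids = grids,
       seeds = rep_seeds,
       fraction = cfg$noise_fraction)
}

#' Write a pipeline report to disk
#'
#' Emits per-edge weight TSVs, weight-summary JSON, the diameter grid,
#' module assignment/discrete/match tables, extreme-strata and pathway
#' TSVs under `outdir`.
#'
#' @param report a [run_all()] report.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, file)
    write.table(df, file.path(outdir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  for (s in names(report$weights)) {
    w <- report$weights[[s]]
    e <- w$network$edges
    e$weight <- w$weights
    tsv(e, sprintf("weights_%s.tsv", s))
    A <- report$landscapes[[s]]$assignment
    tsv(data.frame(node = rownames(A), A, check.names = FALSE),
        sprintf("assignment_%s.tsv", s))
    da <- discrete_assignment(report$landscapes[[s]])
    tsv(data.frame(node = names(da), module = unname(da)),
        sprintf("modules_discrete_%s.tsv", s))
    tsv(report$representation[[s]], sprintf("representation_%s.tsv", s))
  }
  tsv(report$diameters, "diameters.tsv")
  tsv(report$wilcoxon, "wilcoxon.tsv")
  if (!is.null(report$pathways)) tsv(report$pathways, "pathways.tsv")
  summ <- lapply(report$summaries, function(s)
    s[c("n", "median", "mean", "sd", "q1", "q3", "iqr", "min", "max",
        "bin_fractions")])
  jsonlite::write_json(summ, file.path(outdir, "weight_summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$noise))
    jsonlite::write_json(
      list(stability = as.list(report$noise$stability),
           fraction = report$noise$fraction),
      file.path(outdir, "noise_stability.json"),
      auto_unbox = TRUE, digits = NA)
  for (k in names(report$matches))
    tsv(report$matches[[k]], sprintf("match_%s.tsv", k))
  invisible(outdir)
}
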