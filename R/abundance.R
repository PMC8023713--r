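# Abundance construction: normalization, median aggregation, noise.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Quantile-normalize an expression matrix
#'
#' Makes every sample column share the same value distribution (the vector
#' of row-rank means), the standard normalization when pooling microarray
#' samples across series. Within-column rank order is preserved. A
#' single-sample matrix is returned unchanged with a warning.
#'
#' @param em an [expr_matrix].
#' @return The normalized [expr_matrix].
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2) {
    warning("single-sample matrix: quantile normalization skipped")
    return(em)
  }
  v <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(v) <- dimnames(em$values)
  expr_matrix(v, state_label = em$state_label, series_id = em$series_id)
}

#' Aggregate expression matrices of one state to per-gene abundances
#'
#' Samples from all matrices of the state are pooled and the per-gene
#' median of the pooled samples is the gene's abundance. Genes absent from
#' any matrix are dropped (intersection of gene universes).
#'
#' @param matrices list of [expr_matrix] objects sharing a `state_label`.
#' @return Named numeric vector: gene -> abundance.
#' @export
median_aggregate <- function(matrices) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "expr_matrix")))
  states <- unique(vapply(matrices, `[[`, character(1), "state_label"))
  if (length(states) != 1)
    stop("matrices mix state labels: ", paste(states, collapse = ", "))
  genes <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(genes) == 0) stop("empty gene intersection across matrices")
  genes <- sort(genes)
  pooled <- do.call(cbind, lapply(matrices,
                                  function(m) m$values[genes, , drop = FALSE]))
  apply(pooled, 1, median)
}

#' Assemble a gene x state abundance table
#'
#' Genes missing in any state are dropped from all states so the three
#' state networks share one gene universe.
#'
#' @param by_state named list (state label -> named abundance vector, as
#'   from [median_aggregate()]).
#' @return Numeric matrix (genes x states) of class `abundance_table`.
#' @export
abundance_table <- function(by_state) {
  stopifnot(is.list(by_state), length(by_state) >= 1,
            !is.null(names(by_state)))
  genes <- sort(Reduce(intersect, lapply(by_state, names)))
  if (length(genes) == 0) stop("no gene present in every state")
  tab <- vapply(by_state, function(a) a[genes], numeric(length(genes)))
  tab <- matrix(tab, nrow = length(genes),
                dimnames = list(genes, names(by_state)))
  if (!all(is.finite(tab)) || any(tab <= 0))
    stop("abundances must be finite and > 0")
  class(tab) <- c("abundance_table", class(tab))
  tab
}

#' Perturb abundances by a fixed multiplicative noise fraction
#'
#' Each value is independently multiplied by `1 + fraction` or
#' `1 - fraction` with probability 1/2 (the +/-5 percent robustness check,
#' with `fraction = 0.05`). Reproducible for equal seeds; the caller's RNG
#' state is untouched.
#'
#' @param tab an [abundance_table] (or any positive numeric matrix/vector).
#' @param fraction noise fraction in (0, 1); default 0.05.
#' @param seed integer seed.
#' @return Perturbed object of the same shape.
#' @export
perturb_noise <- function(tab, fraction = 0.05, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    stop("noise fraction must lie in (0, 1)")
  stopifnot(is.numeric(seed))
  signs <- with_seed(seed,
                     sample(c(-1, 1), length(tab), replace = TRUE))
  out <- tab * (1 + signs * fraction)
  attributes(out) <- attributes(tab)
  out
}
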