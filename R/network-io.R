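#' @importFrom stats median sd quantile setNames pnorm rnorm
#' @importFrom utils read.delim write.table
NULL

#' Recognised interaction types
#'
#' The typed signaling network distinguishes activating, inhibiting,
#' undirected (association-type) and unknown links.
#' @export
INTERACTION_TYPES <- c("activating", "inhibiting", "undirected", "unknown")

# vocabulary accepted in edge-list files -> canonical type
.interaction_vocab <- c(
  "activating" = "activating", "activate" = "activating", "1" = "activating",
  "inhibiting" = "inhibiting", "inhibit" = "inhibiting", "-1" = "inhibiting",
  "undirected" = "undirected", "pp" = "undirected",
  "association" = "undirected",
  "unknown" = "unknown"
)

#' Construct a typed signaling network
#'
#' A `signaling_network` is a fixed topology shared by all biological
#' states: gene-symbol nodes joined by typed links. Parallel edges of
#' *different* types between the same pair are retained as distinct links
#' (the source network distinguishes activation, inhibition and
#' association between identical pairs); exact duplicates are merged.
#'
#' @param edges data.frame with character columns `source`, `target`,
#'   `type` (each type one of [INTERACTION_TYPES]).
#' @param name network label.
#' @return An object of class `signaling_network` with elements `nodes`
#'   (sorted gene symbols), `edges` (deduplicated data.frame) and `name`.
#' @export
signaling_network <- function(edges, name = "network") {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "type") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      type   = as.character(edges$type),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$type), INTERACTION_TYPES)
  if (length(bad) > 0)
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  if (any(edges$source == "" | edges$target == ""))
    stop("empty node symbol in edge list")
  edges <- edges[!duplicated(edges[c("source", "target", "type")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  net <- list(nodes = sort(unique(c(edges$source, edges$target))),
              edges = edges, name = name)
  class(net) <- "signaling_network"
  net
}

#' @export
print.signaling_network <- function(x, ...) {
  tab <- table(factor(x$edges$type, levels = INTERACTION_TYPES))
  cat(sprintf("signaling_network '%s': %d nodes, %d edges\n", x$name,
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

#' Read a typed edge list (SIF or three-column TSV)
#'
#' Two dialects are auto-detected. A file whose first line is a header
#' containing the words `source` and `target` is read as TSV with columns
#' source, target, interaction; otherwise rows are SIF-style
#' `source interaction target`, separated by tabs or whitespace.
#' Interaction strings outside the recognised vocabulary
#' (activating/activate/1, inhibiting/inhibit/-1, undirected/pp/association,
#' unknown) are mapped to `"unknown"` with a warning.
#'
#' @param path edge-list file.
#' @param name network label (defaults to the file name).
#' @return A [signaling_network].
#' @export
read_network <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty network file: ", path)

  fields <- strsplit(lines, "[ \t]+")
  first <- tolower(fields[[1]])
  tsv <- length(first) >= 2 && "source" %in% first && "target" %in% first
  if (tsv) {
    if (length(lines) < 2) stop("TSV network file has a header but no rows")
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed network row at line %d (need >= 3 columns)",
                 line_no[which(nf < 3)[1]]))
  m <- t(vapply(fields, function(f) f[1:3], character(3)))
  if (tsv) {
    src <- m[, 1]; tgt <- m[, 2]; raw <- m[, 3]
  } else {
    src <- m[, 1]; raw <- m[, 2]; tgt <- m[, 3]
  }
  type <- unname(.interaction_vocab[tolower(raw)])
  if (anyNA(type)) {
    unk <- unique(raw[is.na(type)])
    warning("unrecognised interaction label(s) mapped to 'unknown': ",
            paste(unk, collapse = ", "))
    type[is.na(type)] <- "unknown"
  }
  signaling_network(data.frame(source = src, target = tgt, type = type,
                               stringsAsFactors = FALSE), name = name)
}

#' Write a typed network to SIF or TSV
#'
#' @param net a [signaling_network].
#' @param path output file.
#' @param format `"sif"` (`source<TAB>interaction<TAB>target`) or `"tsv"`
#'   (header `source target interaction`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    writeLines(paste(e$source, e$type, e$target, sep = "\t"), path)
  } else {
    writeLines(c("source\ttarget\tinteraction",
                 paste(e$source, e$target, e$type, sep = "\t")), path)
  }
  invisible(path)
}

#' Convert a signaling network to an igraph object
#'
#' @param net a [signaling_network].
#' @param directed build a directed graph (edge rows keep their
#'   orientation)? Default `FALSE`: the undirected skeleton.
#' @return igraph graph with edge attribute `type`.
#' @export
as_igraph <- function(net, directed = FALSE) {
  g <- igraph::graph_from_data_frame(net$edges, directed = directed,
                                     vertices = net$nodes)
  g
}

#' Restrict a network to measured genes, known link types and the giant
#' component
#'
#' Mirrors the construction of the analysis network: links whose endpoints
#' are not both covered by the expression data, or whose type is unknown,
#' are deleted, and then only the largest connected component of the
#' undirected skeleton is kept. The operation is idempotent.
#'
#' @param net a [signaling_network].
#' @param measured_genes character vector of gene symbols covered by the
#'   expression data.
#' @return Filtered [signaling_network].
#' @export
filter_network <- function(net, measured_genes) {
  stopifnot(length(measured_genes) > 0)
  e <- net$edges
  keep <- e$type != "unknown" &
    e$source %in% measured_genes & e$target %in% measured_genes
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) stop("no edge survives filtering")
  sub <- signaling_network(e, name = net$name)
  g <- as_igraph(sub, directed = FALSE)
  comp <- igraph::components(g, mode = "weak")
  giant <- which.max(comp$csize)
  giant_nodes <- names(comp$membership)[comp$membership == giant]
  e <- e[e$source %in% giant_nodes & e$target %in% giant_nodes, ,
         drop = FALSE]
  signaling_network(e, name = net$name)
}

#' Construct a per-state expression matrix
#'
#' Log2-scale intensities, genes in rows. Duplicate gene symbols must be
#' collapsed before construction; all values must be finite and positive.
#'
#' @param values numeric matrix with gene-symbol rownames and sample-id
#'   colnames.
#' @param state_label biological state ("normal", "adenoma", "carcinoma" or
#'   a free string).
#' @param series_id data-series label.
#' @return Object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, state_label, series_id = "series") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols; collapse probes first")
  if (!all(is.finite(values)) || any(values <= 0))
    stop("expression values must be finite and > 0")
  structure(list(values = values, state_label = state_label,
                 series_id = series_id),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s/%s]: %d genes x %d samples\n",
              x$series_id, x$state_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an expression TSV (genes in rows, sample ids in the header)
#'
#' Duplicate gene rows are collapsed by row-wise (element-wise) median.
#' Non-numeric or non-positive cells raise an error naming the offending
#' gene and sample.
#'
#' @param path TSV file; first column gene symbols, remaining columns
#'   numeric intensities.
#' @inheritParams expr_matrix
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, state_label, series_id = basename(path)) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs >= 1 sample column")
  genes <- df[[1]]
  if (any(is.na(genes) | genes == ""))
    stop(sprintf("empty gene symbol at data row %d",
                 which(is.na(genes) | genes == "")[1]))
  samples <- colnames(df)[-1]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, samples))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[idx[1]], samples[idx[2]]))
  }
  if (any(vals <= 0)) {
    idx <- which(vals <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive expression value at gene '%s', sample '%s'",
                 genes[idx[1]], samples[idx[2]]))
  }
  if (anyDuplicated(genes)) {
    ug <- sort(unique(genes))
    collapsed <- t(vapply(ug, function(g) {
      block <- vals[genes == g, , drop = FALSE]
      apply(block, 2, median)
    }, numeric(ncol(vals))))
    vals <- collapsed
    rownames(vals) <- ug
  } else {
    rownames(vals) <- genes
  }
  expr_matrix(vals, state_label = state_label, series_id = series_id)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene symbols).
#' @param description named character vector, one entry per set.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name: ",
         names(sets)[duplicated(names(sets))][1])
  if (any(lengths(sets) == 0)) stop("empty gene set")
  if (is.null(description))
    description <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: tab-separated `name<TAB>description<TAB>member...`.
#' Duplicate members within a line are dropped (order preserved);
#' duplicate set names are an error.
#'
#' @param path GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("GMT line %d has fewer than 3 fields", which(nf < 3)[1]))
  nm <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, `[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(setNames(sets, nm), setNames(desc, nm))
}

#' Write gene sets in GMT format
#'
#' @param gs a [gene_set_collection].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$description[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
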