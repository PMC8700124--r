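#' Pearson correlation coefficient
#'
#' Sample Pearson correlation of two equal-length vectors. Zero variance in
#' either vector is an error (graph builders skip such pairs with a
#' warning).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
#' @examples
#' pearson(1:5, c(2, 4, 6, 8, 10))
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Undefined correlation: zero-variance vector.")
  }
  cor(x, y)
}

new_correlation_graph <- function(nodes, edges, threshold, node_type,
                                  node_meta = NULL) {
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         node_type = node_type, node_meta = node_meta),
    class = "correlation_graph"
  )
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("<correlation_graph>", length(x$nodes), x$node_type, "nodes,",
      nrow(x$edges), "edges at r >=", x$threshold, "\n")
  invisible(x)
}

# Threshold an r matrix into an undirected edge tibble (i < j, one row per
# pair); `keep` masks rows/cols whose variance is defined.
threshold_edges <- function(r, nodes, threshold, keep = NULL) {
  if (!is.null(keep)) {
    r[!keep, ] <- NA_real_
    r[, !keep] <- NA_real_
  }
  r[lower.tri(r, diag = TRUE)] <- NA_real_
  idx <- which(!is.na(r) & r >= threshold, arr.ind = TRUE)
  tibble(
    from = nodes[idx[, 1]],
    to = nodes[idx[, 2]],
    weight = r[idx]
  )
}

#' Sample-sample correlation graph
#'
#' One node per sample; an undirected edge wherever the Pearson correlation
#' of two samples' abundance vectors (over all proteins) reaches the
#' threshold. Zero-variance samples contribute no edges (with a warning).
#'
#' @param abundance Long-format abundance tibble.
#' @param config A [pipeline_config()] supplying `pearson_threshold`.
#' @param compartment Optional compartment to restrict to (`"synaptic"` or
#'   `"non_synaptic"`); the published readout builds one graph per
#'   compartment.
#' @return A `correlation_graph` over samples (node metadata carries
#'   compartment/age/replicate).
#' @export
build_sample_graph <- function(abundance, config = pipeline_config(),
                               compartment = NULL) {
  abundance <- validate_abundance(abundance)
  w <- abundance_wide(abundance, compartment = compartment)
  if (ncol(w$values) < 2) abort("Need at least 2 samples.")
  sds <- apply(w$values, 2, sd)
  keep <- sds > 0
  if (any(!keep)) {
    warn(paste0("Skipping zero-variance sample(s): ",
                paste(colnames(w$values)[!keep], collapse = ", ")))
  }
  r <- suppressWarnings(cor(w$values))
  edges <- threshold_edges(r, colnames(w$values), config$pearson_threshold,
                           keep = keep)
  new_correlation_graph(colnames(w$values), edges,
                        config$pearson_threshold, "sample",
                        node_meta = w$samples)
}

#' Protein-protein co-expression graph for one compartment
#'
#' One node per protein; an undirected edge wherever the Pearson correlation
#' of two proteins' expression vectors across the compartment's samples
#' reaches the threshold. Zero-variance proteins stay as isolated nodes
#' (with a warning).
#'
#' @param abundance Long-format abundance tibble.
#' @param config A [pipeline_config()].
#' @param compartment Which compartment's samples to correlate over;
#'   required unless `abundance` already holds a single compartment.
#' @return A `correlation_graph` over proteins.
#' @export
build_protein_graph <- function(abundance, config = pipeline_config(),
                                compartment = NULL) {
  abundance <- validate_abundance(abundance)
  present <- unique(as.character(abundance$compartment))
  if (is.null(compartment)) {
    if (length(present) > 1) {
      abort("`compartment` must be given when both compartments are present.")
    }
    compartment <- present
  }
  w <- abundance_wide(abundance, compartment = compartment)
  if (ncol(w$values) < 3) abort("Need at least 3 samples per compartment.")
  sds <- apply(w$values, 1, sd)
  keep <- sds > 0
  if (any(!keep)) {
    warn(sprintf("Skipping %d zero-variance protein(s).", sum(!keep)))
  }
  r <- suppressWarnings(cor(t(w$values)))
  edges <- threshold_edges(r, rownames(w$values), config$pearson_threshold,
                           keep = keep)
  new_correlation_graph(rownames(w$values), edges,
                        config$pearson_threshold, "protein")
}

#' Convert a correlation graph to igraph
#'
#' @param graph A `correlation_graph`.
#' @return An undirected weighted [igraph::igraph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "correlation_graph"))
  igraph::graph_from_data_frame(
    graph$edges,
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  )
}

#' Connected components of a correlation graph
#'
#' Maximal connected node sets, deterministically ordered and numbered by
#' their smallest member (first occurrence in the graph's node order).
#'
#' @param graph A `correlation_graph`.
#' @return Tibble with `node` and `component` (integer id).
#' @export
graph_components <- function(graph) {
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  membership <- comp$membership[graph$nodes]
  # renumber components by first occurrence in node order
  first <- !duplicated(membership)
  relabel <- setNames(seq_len(sum(first)), membership[first])
  tibble(node = graph$nodes,
         component = as.integer(relabel[as.character(membership)]))
}

#' Number of connected components
#'
#' @param graph A `correlation_graph`.
#' @return Integer component count (the graph-fragmentation readout).
#' @export
n_components <- function(graph) {
  max(graph_components(graph)$component)
}

#' Export a correlation graph to GraphML
#'
#' Node attributes carry the sample metadata (compartment, age, replicate)
#' for sample graphs, or cluster membership for protein graphs when
#' `clusters` is supplied.
#'
#' @param graph A `correlation_graph`.
#' @param path Output file path.
#' @param clusters Optional [mcl_cluster()] result for protein graphs.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path, clusters = NULL) {
  g <- as_igraph(graph)
  if (!is.null(graph$node_meta)) {
    meta <- graph$node_meta
    i <- match(igraph::V(g)$name, meta$sample_id)
    igraph::V(g)$compartment <- as.character(meta$compartment)[i]
    igraph::V(g)$age <- as.character(meta$age)[i]
    igraph::V(g)$replicate <- meta$replicate[i]
  }
  if (!is.null(clusters)) {
    mem <- tidy(clusters)
    igraph::V(g)$cluster <- mem$cluster[match(igraph::V(g)$name, mem$node)]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
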