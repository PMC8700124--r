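#' Markov clustering (MCL) of a correlation graph
#'
#' In-house implementation of the MCL procedure: the thresholded correlation
#' graph is turned into a column-stochastic matrix (self-loop weight = the
#' node's maximum incident edge weight), then expansion (matrix power),
#' inflation (elementwise power followed by column renormalisation) and
#' pruning (entries below `mcl_prune` zeroed, columns renormalised) are
#' iterated until the maximum absolute change per cycle drops below
#' `mcl_tol` (or 200 iterations, an error). Clusters are read off the limit
#' matrix via its attractors: attractor systems are the connected components
#' of the non-zero structure among attractor nodes, and every other node
#' joins the system receiving most of its flow (exact ties go to the system
#' containing the smallest node id). Isolated nodes become singletons, and
#' each connected component is clustered independently (MCL never merges
#' across components).
#'
#' @param graph A `correlation_graph` (see [build_protein_graph()]).
#' @param config A [pipeline_config()] supplying `mcl_inflation`,
#'   `mcl_expansion`, `mcl_prune`, `mcl_tol`.
#' @param weighted Use edge correlations as transition mass (default); if
#'   `FALSE` all edges get unit weight (the exact weighting used by the
#'   original network tool is undocumented, so both variants are offered).
#' @return An object of class `mcl_clusters`: membership tibble plus
#'   convergence diagnostics. Cluster ids are numbered by their smallest
#'   member in graph node order. Use [tidy()] for the membership,
#'   [glance()] for a one-row summary.
#' @export
mcl_cluster <- function(graph, config = pipeline_config(), weighted = TRUE) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (length(graph$nodes) == 0) abort("Cannot cluster an empty graph.")

  comp <- graph_components(graph)
  edges <- graph$edges
  if (!weighted && nrow(edges) > 0) edges$weight <- 1

  membership <- integer(length(graph$nodes))
  names(membership) <- graph$nodes
  next_id <- 1L
  max_iter_used <- 0L

  for (ci in unique(comp$component)) {
    nodes_c <- comp$node[comp$component == ci]
    if (length(nodes_c) == 1) {
      membership[nodes_c] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- edges[edges$from %in% nodes_c, , drop = FALSE]
    A <- matrix(0, length(nodes_c), length(nodes_c),
                dimnames = list(nodes_c, nodes_c))
    i <- match(sub$from, nodes_c)
    j <- match(sub$to, nodes_c)
    A[cbind(i, j)] <- sub$weight
    A[cbind(j, i)] <- sub$weight

    res <- mcl_core(A,
                    inflation = config$mcl_inflation,
                    expansion = config$mcl_expansion,
                    prune = config$mcl_prune,
                    tol = config$mcl_tol)
    max_iter_used <- max(max_iter_used, res$iterations)
    for (cl in res$clusters) {
      membership[nodes_c[cl]] <- next_id
      next_id <- next_id + 1L
    }
  }

  # renumber clusters by smallest member position in node order
  first <- membership[!duplicated(membership)]
  relabel <- setNames(seq_along(first), first)
  membership <- as.integer(relabel[as.character(membership)])

  structure(
    list(
      membership = tibble(node = graph$nodes, cluster = membership),
      n_clusters = max(membership),
      iterations = max_iter_used,
      inflation = config$mcl_inflation,
      expansion = config$mcl_expansion,
      weighted = weighted
    ),
    class = "mcl_clusters"
  )
}

# Core MCL loop on one dense adjacency matrix (one connected component).
mcl_core <- function(A, inflation, expansion, prune, tol, max_iter = 200L) {
  n <- nrow(A)
  diag(A) <- apply(A, 2, max)            # self-loop = max incident weight
  M <- normalise_columns(A)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    M_old <- M
    E <- M
    for (e in seq_len(expansion - 1L)) E <- E %*% M
    M <- E^inflation
    M <- normalise_columns(M)
    M[M < prune] <- 0
    M <- normalise_columns(M)
    d <- max(abs(M - M_old))
    if (d < tol) break
    if (iter >= max_iter) {
      abort(sprintf(
        "MCL failed to converge after %d iterations (last max change %.3g, %d nodes, inflation %.2f).",
        iter, d, n, inflation
      ))
    }
  }

  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) {
    # pathological limit with no attractors: fall back to the non-zero
    # structure of the whole limit matrix
    return(list(clusters = structure_components(M > 0 | t(M) > 0),
                iterations = iter))
  }

  S <- M[attractors, attractors, drop = FALSE]
  sys_of_attractor <- components_of(S > 0 | t(S) > 0)
  n_sys <- max(sys_of_attractor)

  # flow of every node into each attractor system (columns = source nodes)
  mass <- matrix(0, n_sys, n)
  for (s in seq_len(n_sys)) {
    rows <- attractors[sys_of_attractor == s]
    mass[s, ] <- colSums(M[rows, , drop = FALSE])
  }
  smallest_member <- vapply(seq_len(n_sys), function(s) {
    min(attractors[sys_of_attractor == s])
  }, integer(1))

  assign_sys <- integer(n)
  clusters <- vector("list", n_sys)
  extra <- list()
  for (v in seq_len(n)) {
    m <- mass[, v]
    if (all(m == 0)) {
      extra[[length(extra) + 1L]] <- v     # unreached: its own singleton
      next
    }
    best <- which(m == max(m))
    if (length(best) > 1) best <- best[which.min(smallest_member[best])]
    assign_sys[v] <- best
  }
  for (s in seq_len(n_sys)) clusters[[s]] <- which(assign_sys == s)
  clusters <- c(clusters[lengths(clusters) > 0], extra)
  # deterministic order by smallest member
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  list(clusters = clusters, iterations = iter)
}

normalise_columns <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    # a fully pruned column re-anchors on its own node
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2, cs, "/")
}

# connected components of a logical adjacency matrix; integer labels in
# order of first occurrence
components_of <- function(adj) {
  n <- nrow(adj)
  label <- integer(n)
  current <- 0L
  for (v in seq_len(n)) {
    if (label[v] > 0) next
    current <- current + 1L
    queue <- v
    label[v] <- current
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[u, ] & label == 0)
      label[nb] <- current
      queue <- c(queue, nb)
    }
  }
  label
}

structure_components <- function(adj) {
  lab <- components_of(adj)
  lapply(seq_len(max(lab)), function(s) which(lab == s))
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat("<mcl_clusters>", x$n_clusters, "clusters over",
      nrow(x$membership), "nodes (inflation", x$inflation,
      ", converged in <=", x$iterations, "iterations)\n")
  invisible(x)
}

#' Mean temporal profiles of protein clusters
#'
#' For each cluster, the mean over member proteins of the per-age group
#' means within one compartment.
#'
#' @param clusters An [mcl_cluster()] result over proteins.
#' @param abundance Long-format abundance tibble.
#' @param compartment Compartment whose samples define the profile; required
#'   when both compartments are present.
#' @return Tibble with `cluster`, `age`, `mean_abundance`, `n_members`.
#' @export
cluster_profiles <- function(clusters, abundance, compartment = NULL) {
  stopifnot(inherits(clusters, "mcl_clusters"))
  abundance <- validate_abundance(abundance)
  present <- unique(as.character(abundance$compartment))
  if (is.null(compartment)) {
    if (length(present) > 1) {
      abort("`compartment` must be given when both compartments are present.")
    }
    compartment <- present
  }
  unknown <- setdiff(clusters$membership$node, unique(abundance$protein_id))
  if (length(unknown) > 0) {
    abort(paste0("Cluster member(s) not in abundance table: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  gm <- abundance %>%
    filter(.data$compartment == !!compartment) %>%
    group_means()
  gm %>%
    dplyr::inner_join(clusters$membership,
                      by = c(protein_id = "node")) %>%
    group_by(.data$cluster, .data$age) %>%
    summarise(mean_abundance = mean(.data$mean_abundance),
              n_members = dplyr::n_distinct(.data$protein_id),
              .groups = "drop") %>%
    arrange(.data$cluster, .data$age)
}
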