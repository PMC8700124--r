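#' Tidy an MCL clustering
#'
#' @param x An [mcl_cluster()] result.
#' @param ... Unused.
#' @return The membership tibble (`node`, `cluster`).
#' @method tidy mcl_clusters
#' @export
tidy.mcl_clusters <- function(x, ...) {
  x$membership
}

#' One-row summary of an MCL clustering
#'
#' @inheritParams tidy.mcl_clusters
#' @return Tibble with `n_nodes`, `n_clusters`, `n_singletons`,
#'   `iterations`, `inflation`.
#' @method glance mcl_clusters
#' @export
glance.mcl_clusters <- function(x, ...) {
  sizes <- table(x$membership$cluster)
  tibble(
    n_nodes = nrow(x$membership),
    n_clusters = x$n_clusters,
    n_singletons = sum(sizes == 1),
    iterations = x$iterations,
    inflation = x$inflation
  )
}

#' Tidy a candidate funnel
#'
#' @param x A [run_funnel()] result.
#' @param ... Unused.
#' @return The per-protein candidate table.
#' @method tidy candidate_funnel
#' @export
tidy.candidate_funnel <- function(x, ...) {
  x$candidates
}

#' One-row summary of a candidate funnel
#'
#' @inheritParams tidy.candidate_funnel
#' @return Tibble of funnel stage counts (one column per stage).
#' @method glance candidate_funnel
#' @export
glance.candidate_funnel <- function(x, ...) {
  as_tibble(as.list(setNames(x$counts$n, x$counts$stage)))
}
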