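# Build a long abundance tibble from a proteins x samples matrix and a
# (compartment, age, replicate) design; used to hand-craft tiny datasets.
abundance_from_matrix <- function(values, compartment, age, replicate,
                                  unique_peptides = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%03d", seq_len(n))
  }
  sample_id <- paste(compartment, age, replicate, sep = "_")
  ns <- length(sample_id)
  if (is.null(unique_peptides)) unique_peptides <- rep(5L, n)
  tibble::tibble(
    protein_id = rep(rownames(values), each = ns),
    sample_id = rep(sample_id, times = n),
    compartment = factor(rep(compartment, times = n),
                         levels = c("synaptic", "non_synaptic")),
    age = factor(rep(age, times = n),
                 levels = c("young", "mid", "old"), ordered = TRUE),
    replicate = rep(replicate, times = n),
    abundance = as.vector(t(values)),
    unique_peptides = rep(as.integer(unique_peptides), each = ns)
  )
}

# full 2-compartment x 3-age x reps design from per-(protein, group) means,
# with optional multiplicative log-normal noise
abundance_from_means <- function(mean_fun, n_proteins, reps = 3,
                                 noise_sd = 0, seed = 1) {
  comps <- rep(c("synaptic", "non_synaptic"), each = 3 * reps)
  ages <- rep(rep(c("young", "mid", "old"), each = reps), times = 2)
  repl <- rep(seq_len(reps), times = 6)
  values <- matrix(0, n_proteins, length(comps))
  withr::with_seed(seed, {
    for (p in seq_len(n_proteins)) {
      mu <- mapply(function(cmp, a) mean_fun(p, cmp, a), comps, ages)
      values[p, ] <- mu * exp(rnorm(length(mu), 0, noise_sd))
    }
  })
  abundance_from_matrix(values, comps, ages, repl)
}

# random correlation-graph-shaped object for fuzzing MCL directly
random_graph <- function(n, p_edge = 0.2, weighted = TRUE, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- utils::combn(n, 2)
    keep <- runif(ncol(pairs)) < p_edge
    edges <- tibble::tibble(
      from = nodes[pairs[1, keep]],
      to = nodes[pairs[2, keep]],
      weight = if (weighted) runif(sum(keep), 0.5, 1) else
        rep(1, sum(keep))
    )
    mitofunnel:::new_correlation_graph(nodes, edges, 0, "protein")
  })
}

# dense symmetric adjacency matrix of a correlation_graph (for oracle MCL)
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  A
}

# membership tibble -> list of integer clusters (positions in node order)
membership_to_partition <- function(membership, nodes) {
  idx <- match(membership$node, nodes)
  unname(lapply(split(idx, membership$cluster), sort))
}
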