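# Independent oracles, deliberately coded from first principles (loops and
# closed forms) so they share no code path with the package implementation.

# textbook sum-of-squares one-way ANOVA
oracle_anova_p <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Monte-Carlo post-hoc power: simulate normal one-way layouts at the given
# group means and common sd, count level-alpha rejections (vectorised)
oracle_power_mc <- function(means, sd_within, n_per_group, alpha = 0.05,
                            nrep = 50000, seed = 42) {
  withr::with_seed(seed, {
    k <- length(means)
    n <- k * n_per_group
    y <- matrix(
      stats::rnorm(nrep * n,
                   mean = rep(rep(means, each = n_per_group), times = nrep),
                   sd = sd_within),
      nrow = nrep, byrow = TRUE
    )
    g <- rep(seq_len(k), each = n_per_group)
    gm <- sapply(seq_len(k), function(j) rowMeans(y[, g == j, drop = FALSE]))
    grand <- rowMeans(y)
    ssb <- n_per_group * rowSums((gm - grand)^2)
    sst <- rowSums((y - grand)^2)
    ssw <- sst - ssb
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    mean(f > stats::qf(1 - alpha, k - 1, n - k))
  })
}

# direct-formula Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# hypergeometric upper-tail sum via binomial coefficients
oracle_fisher_tail <- function(observed, term, background, selection) {
  hi <- min(term, selection)
  total <- 0
  for (i in observed:hi) {
    total <- total + choose(term, i) * choose(background - term, selection - i)
  }
  total / choose(background, selection)
}

# sorted step-up Benjamini-Hochberg with explicit cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (r in m:1) {
    running <- min(running, p[o[r]] * m / r)
    adj[o[r]] <- running
  }
  adj
}

# plain-loop breadth-first connected components over an edge list
oracle_components <- function(nodes, from, to) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  label <- setNames(rep(0L, length(nodes)), nodes)
  cur <- 0L
  for (v in nodes) {
    if (label[v] > 0) next
    cur <- cur + 1L
    queue <- v
    label[v] <- cur
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (label[w] == 0) {
          label[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  label
}

# reference MCL, written independently: explicit loop normalisation and the
# classical "clusters = components of rows with positive diagonal" readout
oracle_mcl <- function(A, inflation = 2.2, expansion = 2, prune = 1e-6,
                       tol = 1e-8, max_iter = 200) {
  n <- nrow(A)
  for (v in seq_len(n)) A[v, v] <- max(A[, v])
  col_norm <- function(M) {
    for (j in seq_len(ncol(M))) {
      s <- sum(M[, j])
      if (s == 0) M[j, j] <- 1 else M[, j] <- M[, j] / s
    }
    M
  }
  M <- col_norm(A)
  for (it in seq_len(max_iter)) {
    old <- M
    P <- diag(n)
    for (e in seq_len(expansion)) P <- P %*% M
    M <- col_norm(P^inflation)
    M[M < prune] <- 0
    M <- col_norm(M)
    if (max(abs(M - old)) < tol) break
  }
  # nodes i, j share a cluster when they receive flow from a common
  # attractor row
  attractor <- which(diag(M) > 0)
  member <- rep(0L, n)
  cl <- 0L
  for (a in attractor) {
    support <- which(M[a, ] > 0)
    hit <- unique(member[support][member[support] > 0])
    if (length(hit) == 0) {
      cl <- cl + 1L
      member[support] <- cl
    } else {
      keep <- min(hit)
      member[support] <- keep
      member[member %in% setdiff(hit, keep)] <- keep
    }
  }
  for (v in which(member == 0L)) {       # unreached nodes are singletons
    cl <- cl + 1L
    member[v] <- cl
  }
  cl_list <- split(seq_len(n), member)
  unname(lapply(cl_list, as.integer))
}

# canonical form of a partition for comparison
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}
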