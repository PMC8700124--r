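#' ArcSinh variance-stabilising transform
#'
#' `ln(x + sqrt(x^2 + 1))`, the transform applied to normalised abundances
#' before the one-way ANOVA. Strictly increasing; `arcsinh_transform(0) = 0`.
#'
#' @param x Non-negative finite numeric vector.
#' @return Transformed vector.
#' @export
#' @examples
#' arcsinh_transform(c(0, 1, 100))
arcsinh_transform <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and >= 0.")
  }
  asinh(x)
}

# Vectorised one-way fixed-effects ANOVA over matrix rows.
# Y: rows = features, columns = observations; groups: factor over columns.
# Returns p-values and post-hoc power at `alpha` (noncentral F with
# lambda = SSB / MSW, the observed-effect noncentrality).
row_anova <- function(Y, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(Y)
  if (k < 2) abort("ANOVA needs >= 2 groups.")
  nj <- as.vector(table(groups))
  if (any(nj == 0)) abort("ANOVA group with 0 observations.")
  dfb <- k - 1
  dfw <- n - k
  if (dfw < 1) abort("ANOVA needs at least 1 residual degree of freedom.")

  G <- stats::model.matrix(~ groups - 1)
  Gm <- (Y %*% G) %*% diag(1 / nj, k)          # group means
  grand <- rowMeans(Y)
  ssb <- as.vector((Gm - grand)^2 %*% nj)
  sst <- rowSums(Y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)

  tol <- 1e-11 * pmax(rowSums(Y^2), 1)
  within_zero <- ssw <= tol
  msw <- ssw / dfw
  ok <- !within_zero
  p <- ifelse(ssb > tol, 0, 1)
  power <- ifelse(ssb > tol, 1, alpha)
  if (any(ok)) {
    f <- (ssb[ok] / dfb) / msw[ok]
    p[ok] <- pf(f, dfb, dfw, lower.tail = FALSE)
    fcrit <- qf(1 - alpha, dfb, dfw)
    power[ok] <- pf(fcrit, dfb, dfw, ncp = ssb[ok] / msw[ok],
                    lower.tail = FALSE)
  }
  power <- pmin(pmax(power, 0), 1)

  list(p = p, power = power, ssb = ssb, ssw = ssw, dfb = dfb, dfw = dfw)
}

#' One-way ANOVA p-value across groups
#'
#' Fixed-effects one-way ANOVA F-test. Degenerate conventions: zero
#' within-group variance with differing means gives p = 0; all values
#' identical gives p = 1. Values should already be ArcSinh-transformed by
#' the caller when used on abundances.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor (e.g. age), same length as `values`.
#' @return The F-test p-value.
#' @export
#' @examples
#' anova_p(c(1, 2, 3, 1, 2, 3, 1, 2, 3), gl(3, 3))
anova_p <- function(values, groups) {
  row_anova(matrix(values, nrow = 1), groups)$p
}

#' Post-hoc power of a one-way ANOVA
#'
#' Observed-effect power at level `alpha` via the noncentral F distribution:
#' the noncentrality is the between-group sum of squares of the observed
#' group means divided by the pooled within-group mean square
#' (`lambda = n_total x var_between(means) / var_within`). Zero
#' within-variance gives power 1 when the means differ and `alpha` when not.
#'
#' @inheritParams anova_p
#' @param alpha Significance level of the test whose power is evaluated.
#' @return Power in [0, 1].
#' @export
anova_power <- function(values, groups, alpha = 0.05) {
  row_anova(matrix(values, nrow = 1), groups, alpha = alpha)$power
}

#' Maximum fold change across group means
#'
#' `max(means) / min(means)`; always >= 1.
#'
#' @param means Positive group means (e.g. per-age means of one protein).
#' @return The max/min ratio.
#' @export
#' @examples
#' max_fold_change(c(100, 110, 125))
max_fold_change <- function(means) {
  if (any(!is.finite(means)) || any(means <= 0)) {
    abort("Group means must be positive and finite.")
  }
  max(means) / min(means)
}

#' Per-protein filtering statistics
#'
#' For each protein within each compartment: the one-way ANOVA p-value
#' across the three age groups on ArcSinh-transformed abundances, the
#' post-hoc power of that ANOVA at `config$alpha`, the max/min fold change
#' of the (untransformed) age-group means, and the unique-peptide count.
#'
#' @param abundance Long-format abundance tibble (both compartments allowed).
#' @param config A [pipeline_config()].
#' @return Tibble with `protein_id`, `compartment`, `anova_p`, `power`,
#'   `max_fold_change`, `unique_peptides`, in input protein order within
#'   compartment.
#' @export
feature_stats <- function(abundance, config = pipeline_config()) {
  abundance <- validate_abundance(abundance)
  comps <- levels(droplevels(abundance$compartment))
  purrr::map_dfr(comps, function(cmp) {
    w <- abundance_wide(abundance, compartment = cmp)
    ages <- w$samples$age
    res <- row_anova(asinh(w$values), ages, alpha = config$alpha)
    # age-group means on the raw scale for the fold-change statistic
    G <- stats::model.matrix(~ droplevels(as.factor(ages)) - 1)
    nj <- colSums(G)
    gm <- (w$values %*% G) %*% diag(1 / nj, length(nj))
    up <- abundance %>%
      filter(.data$compartment == cmp) %>%
      distinct(.data$protein_id, .data$unique_peptides)
    tibble(
      protein_id = rownames(w$values),
      compartment = factor(cmp, levels = compartment_levels()),
      anova_p = unname(res$p),
      power = unname(res$power),
      max_fold_change = unname(apply(gm, 1, max) / apply(gm, 1, min))
    ) %>%
      left_join(up, by = "protein_id")
  })
}

#' Feature-level statistical filter
#'
#' Retains proteins (per compartment) with post-hoc power >=
#' `config$power_min`, max fold change >= `config$fc_min` and ANOVA p <=
#' `config$alpha`. Row order is preserved; the filter is idempotent.
#'
#' @param stats A [feature_stats()] tibble (or any tibble with `power`,
#'   `max_fold_change`, `anova_p` columns).
#' @param config A [pipeline_config()].
#' @return The retained subset of `stats`.
#' @export
filter_features <- function(stats, config = pipeline_config()) {
  filter(stats,
         .data$power >= config$power_min,
         .data$max_fold_change >= config$fc_min,
         .data$anova_p <= config$alpha)
}

#' Protein-level peptide/significance filter
#'
#' Retains proteins with `unique_peptides >= config$min_unique_peptides` and
#' ANOVA p <= `config$alpha` (both boundaries inclusive).
#'
#' @inheritParams filter_features
#' @return The retained subset of `stats`.
#' @export
filter_proteins <- function(stats, config = pipeline_config()) {
  filter(stats,
         .data$unique_peptides >= config$min_unique_peptides,
         .data$anova_p <= config$alpha)
}

#' Flag filter outcomes without dropping rows
#'
#' Adds logical `pass_feature` and `pass_protein` columns to a
#' [feature_stats()] table; used by [run_pipeline()] to emit the full
#' per-protein statistics artifact.
#'
#' @inheritParams filter_features
#' @return `stats` with two added logical columns.
#' @export
flag_filters <- function(stats, config = pipeline_config()) {
  mutate(stats,
         pass_feature = .data$power >= config$power_min &
           .data$max_fold_change >= config$fc_min &
           .data$anova_p <= config$alpha,
         pass_protein = .data$unique_peptides >= config$min_unique_peptides &
           .data$anova_p <= config$alpha)
}

#' Proteins common to two datasets
#'
#' Set intersection of protein identifiers, in the order of the first input.
#'
#' @param x,y Long abundance tibbles (or anything with a `protein_id`
#'   column), or plain character vectors of ids.
#' @return Character vector of shared protein ids.
#' @export
common_proteins <- function(x, y) {
  ids <- function(z) if (is.character(z)) z else unique(z$protein_id)
  ix <- ids(x)
  ix[ix %in% ids(y)]
}

#' Count proteins altered by more than a relative threshold
#'
#' Number of proteins per compartment whose max/min age-group-mean ratio
#' exceeds `1 + threshold` (the ">20% altered" census at the default).
#'
#' @param abundance Long-format abundance tibble.
#' @param threshold Relative change threshold (default 0.2, i.e. 20%).
#' @return Tibble with `compartment` and `n_altered`.
#' @export
count_altered <- function(abundance, threshold = 0.2) {
  group_means(abundance) %>%
    group_by(.data$protein_id, .data$compartment) %>%
    summarise(fc = max(.data$mean_abundance) / min(.data$mean_abundance),
              .groups = "drop") %>%
    group_by(.data$compartment) %>%
    summarise(n_altered = sum(.data$fc > 1 + threshold), .groups = "drop")
}
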