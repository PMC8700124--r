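#' Classify a temporal expression trend
#'
#' Rule-based, vectorised classification of (young, mid, old) mean profiles.
#' With `r1 = mid/young`, `r2 = old/mid` and band edges `hi = 1 + epsilon`,
#' `lo = 1/(1 + epsilon)`:
#' * `steady_up`: r1 >= hi and r2 >= hi;
#' * `steady_down`: r1 <= lo and r2 <= lo;
#' * `late_up`: lo < r1 < hi and r2 >= hi;
#' * `late_down`: lo < r1 < hi and r2 <= lo;
#' * `other`: anything else.
#'
#' @param young,mid,old Positive mean abundances (vectorised).
#' @param epsilon Relative-change threshold (> 0; default 0.2 = a 20% step).
#' @return Character vector of trend labels.
#' @export
#' @examples
#' classify_trend(100, 130, 169)        # steady_up
#' classify_trend(100, 105, 140)        # late_up
classify_trend <- function(young, mid, old, epsilon = 0.2) {
  if (epsilon <= 0) abort("`epsilon` must be > 0.")
  v <- c(young, mid, old)
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("Profile means must be positive and finite.")
  }
  r1 <- mid / young
  r2 <- old / mid
  hi <- 1 + epsilon
  lo <- 1 / (1 + epsilon)
  within <- r1 > lo & r1 < hi
  dplyr::case_when(
    r1 >= hi & r2 >= hi ~ "steady_up",
    r1 <= lo & r2 <= lo ~ "steady_down",
    within & r2 >= hi ~ "late_up",
    within & r2 <= lo ~ "late_down",
    TRUE ~ "other"
  )
}

#' Trend labels for cluster mean profiles
#'
#' Applies [classify_trend()] to each cluster's mean temporal profile.
#'
#' @param profiles A [cluster_profiles()] tibble.
#' @param epsilon Trend threshold, see [classify_trend()].
#' @return Tibble with `cluster`, `trend`, `n_members`.
#' @export
cluster_trends <- function(profiles, epsilon = 0.2) {
  wide <- profiles %>%
    select("cluster", "age", "mean_abundance", "n_members") %>%
    tidyr::pivot_wider(names_from = "age", values_from = "mean_abundance")
  wide %>%
    mutate(trend = classify_trend(.data$young, .data$mid, .data$old,
                                  epsilon = epsilon)) %>%
    select("cluster", "trend", "n_members")
}

#' Proteins belonging to clusters with trends of interest
#'
#' Union of the member proteins of every cluster whose trend label is in
#' `classes`, reported per class.
#'
#' @param clusters An [mcl_cluster()] result.
#' @param trends A [cluster_trends()] tibble for the same clustering.
#' @param classes Trend classes of interest (default: the four age-tractable
#'   classes).
#' @return Tibble with `trend` and `protein_id`.
#' @export
trend_candidates <- function(clusters, trends,
                             classes = c("steady_up", "steady_down",
                                         "late_up", "late_down")) {
  stopifnot(inherits(clusters, "mcl_clusters"))
  trends %>%
    filter(.data$trend %in% classes) %>%
    dplyr::inner_join(clusters$membership, by = "cluster",
                      relationship = "many-to-many") %>%
    distinct(.data$trend, protein_id = .data$node)
}

#' Subtract cross-compartment common candidates
#'
#' For each trend class, proteins showing that trend in both compartments
#' are eliminated (they are unlikely to drive compartment-specific
#' vulnerability); the per-class symmetric differences are unioned into the
#' candidate set, in deterministic first-appearance order (synaptic table
#' first).
#'
#' @param syn,nonsyn [trend_candidates()] tibbles for the synaptic and
#'   non-synaptic clusterings.
#' @return Tibble with `protein_id`, `trend`, `compartment` (the compartment
#'   whose cluster contributed the protein), one row per retained
#'   (protein, trend, compartment).
#' @export
subtract_common <- function(syn, nonsyn) {
  both <- bind_rows(
    mutate(syn, compartment = "synaptic"),
    mutate(nonsyn, compartment = "non_synaptic")
  )
  common <- dplyr::inner_join(
    distinct(syn, .data$trend, .data$protein_id),
    distinct(nonsyn, .data$trend, .data$protein_id),
    by = c("trend", "protein_id")
  )
  dplyr::anti_join(both, common, by = c("trend", "protein_id")) %>%
    select("protein_id", "trend", "compartment")
}

#' Ratio-to-young temporal profiles
#'
#' Per protein and compartment, the age-group mean divided by the young
#' group mean (so young = 1 by construction); the published convention for
#' comparing compartments that were normalised as separate experiments.
#'
#' @param abundance Long-format abundance tibble.
#' @param compartment Optional single compartment to restrict to.
#' @return Tibble with `protein_id`, `compartment`, `age`, `ratio`.
#' @export
ratio_to_young <- function(abundance, compartment = NULL) {
  gm <- group_means(abundance)
  if (!is.null(compartment)) {
    gm <- filter(gm, .data$compartment == !!compartment)
  }
  gm %>%
    group_by(.data$protein_id, .data$compartment) %>%
    mutate(ratio = .data$mean_abundance /
             .data$mean_abundance[.data$age == "young"]) %>%
    ungroup() %>%
    select("protein_id", "compartment", "age", "ratio")
}

# wide cross-compartment log2 ratios of the ratio-to-young profiles
cross_compartment_ratios <- function(ratios) {
  if (nrow(ratios) == 0) {
    return(tibble(protein_id = character(), mid_log2_ratio = numeric(),
                  old_log2_ratio = numeric()))
  }
  ratios %>%
    tidyr::pivot_wider(names_from = c("compartment", "age"),
                       values_from = "ratio") %>%
    mutate(
      mid_log2_ratio = log2(.data$synaptic_mid / .data$non_synaptic_mid),
      old_log2_ratio = log2(.data$synaptic_old / .data$non_synaptic_old)
    ) %>%
    select("protein_id", "mid_log2_ratio", "old_log2_ratio")
}

#' Archetypal spatiotemporal profile filter
#'
#' Keeps candidates whose ratio-to-young profiles correspond across
#' compartments at mid-age (|log2 synaptic/non-synaptic ratio| <=
#' `concord_tau`; young is 1:1 by construction) and then demarcate at old
#' age (|log2 ratio| > the demarcation threshold, by default `concord_tau`
#' itself).
#'
#' @param candidates Character vector of protein ids (or a tibble with a
#'   `protein_id` column), e.g. the [subtract_common()] output.
#' @param ratios A [ratio_to_young()] tibble covering both compartments.
#' @param config A [pipeline_config()] supplying `concord_tau`.
#' @param demarcation Old-age |log2 ratio| that must be exceeded (strictly);
#'   defaults to `config$concord_tau`.
#' @return Tibble with `protein_id`, `mid_log2_ratio`, `old_log2_ratio` for
#'   the retained proteins.
#' @export
archetypal_filter <- function(candidates, ratios,
                              config = pipeline_config(),
                              demarcation = config$concord_tau) {
  ids <- if (is.character(candidates)) candidates else
    unique(candidates$protein_id)
  cc <- cross_compartment_ratios(filter(ratios, .data$protein_id %in% ids))
  missing <- setdiff(ids, cc$protein_id[stats::complete.cases(cc)])
  if (length(missing) > 0) {
    abort(paste0("Missing profile in one compartment for: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  cc <- cc[match(ids, cc$protein_id), , drop = FALSE]
  filter(cc,
         abs(.data$mid_log2_ratio) <= config$concord_tau,
         abs(.data$old_log2_ratio) > demarcation)
}

#' Old-age cross-compartment fold-change filter
#'
#' Keeps proteins whose old-age synaptic vs non-synaptic expression differs
#' by at least `divergence_fold` in either direction
#' (|log2 ratio| >= log2(divergence_fold)).
#'
#' @param archetypal An [archetypal_filter()] tibble (needs
#'   `old_log2_ratio`).
#' @param divergence_fold Fold threshold (default 2).
#' @return The retained subset.
#' @export
fold_change_filter <- function(archetypal, divergence_fold = 2) {
  filter(archetypal, abs(.data$old_log2_ratio) >= log2(divergence_fold))
}

#' Run the full candidate-prioritisation funnel
#'
#' End-to-end, deterministic pipeline over a two-compartment timecourse:
#' 1. restrict to proteins common to both compartments;
#' 2. per compartment, compute [feature_stats()] and retain proteins passing
#'    both the feature filter (power/fold-change/p) and the protein filter
#'    (unique peptides/p);
#' 3. per compartment, build the protein co-expression graph at the Pearson
#'    threshold, cluster it with [mcl_cluster()], and label each cluster's
#'    mean profile with [classify_trend()];
#' 4. pool the member proteins of trend-of-interest clusters and apply the
#'    cross-compartment [subtract_common()] step (the trend-candidate set);
#' 5. apply [archetypal_filter()] and [fold_change_filter()] on the
#'    ratio-to-young profiles.
#'
#' @param abundance Long-format abundance tibble containing both
#'   compartments.
#' @param config A [pipeline_config()].
#' @param trend_level `"cluster"` (default; classify MCL cluster mean
#'   profiles, as published) or `"protein"` (classify each retained protein
#'   individually, bypassing cluster granularity).
#' @param pooled_subtraction If `TRUE`, the subtraction pools all four trend
#'   classes before removing cross-compartment common proteins instead of
#'   matching class-by-class.
#' @return An object of class `candidate_funnel` with
#'   * `candidates`: per-protein table over the common universe
#'     (`protein_id`, `trend_synaptic`, `trend_non_synaptic`,
#'     `mid_log2_ratio`, `old_log2_ratio`, `in_trend_set`, `archetypal`,
#'     `pass_2fold`);
#'   * `counts`: funnel stage counts;
#'   * per-compartment diagnostics (retained ids, cluster count).
#'   [tidy()] returns the candidate table, [glance()] the stage counts.
#' @export
run_funnel <- function(abundance, config = pipeline_config(),
                       trend_level = c("cluster", "protein"),
                       pooled_subtraction = FALSE) {
  trend_level <- match.arg(trend_level)
  abundance <- validate_abundance(abundance)

  syn <- filter(abundance, .data$compartment == "synaptic")
  nonsyn <- filter(abundance, .data$compartment == "non_synaptic")
  if (nrow(syn) == 0 || nrow(nonsyn) == 0) {
    abort("`abundance` must contain both compartments.")
  }
  universe <- common_proteins(syn, nonsyn)
  abundance <- filter(abundance, .data$protein_id %in% universe)

  stats <- feature_stats(abundance, config)
  retained <- stats %>%
    flag_filters(config) %>%
    filter(.data$pass_feature, .data$pass_protein)

  per_comp <- purrr::map(
    setNames(compartment_levels(), compartment_levels()),
    function(cmp) {
      ids <- retained$protein_id[retained$compartment == cmp]
      if (length(ids) == 0) {
        return(list(ids = character(), clusters = NULL,
                    trends = tibble(cluster = integer(),
                                    trend = character(),
                                    n_members = integer()),
                    sets = tibble(trend = character(),
                                  protein_id = character())))
      }
      sub <- filter(abundance, .data$protein_id %in% ids,
                    .data$compartment == cmp)
      if (trend_level == "protein") {
        gm <- group_means(sub) %>%
          tidyr::pivot_wider(id_cols = "protein_id", names_from = "age",
                             values_from = "mean_abundance")
        sets <- gm %>%
          mutate(trend = classify_trend(.data$young, .data$mid, .data$old,
                                        epsilon = config$trend_epsilon)) %>%
          filter(.data$trend != "other") %>%
          select("trend", "protein_id")
        return(list(ids = ids, clusters = NULL,
                    trends = tibble(cluster = integer(),
                                    trend = character(),
                                    n_members = integer()),
                    sets = sets))
      }
      g <- suppressWarnings(build_protein_graph(sub, config,
                                                compartment = cmp))
      cl <- mcl_cluster(g, config)
      prof <- cluster_profiles(cl, sub, compartment = cmp)
      tr <- cluster_trends(prof, epsilon = config$trend_epsilon)
      sets <- trend_candidates(cl, tr)
      list(ids = ids, clusters = cl, trends = tr, sets = sets)
    }
  )

  syn_sets <- per_comp$synaptic$sets
  nonsyn_sets <- per_comp$non_synaptic$sets
  if (pooled_subtraction) {
    syn_sets$trend <- "pooled"
    nonsyn_sets$trend <- "pooled"
    syn_sets <- distinct(syn_sets)
    nonsyn_sets <- distinct(nonsyn_sets)
  }
  trend_set <- subtract_common(syn_sets, nonsyn_sets)
  trend_ids <- unique(trend_set$protein_id)

  ratios <- ratio_to_young(abundance)
  cc <- cross_compartment_ratios(ratios)
  arch <- if (length(trend_ids) > 0) {
    archetypal_filter(trend_ids, ratios, config)
  } else {
    tibble(protein_id = character(), mid_log2_ratio = numeric(),
           old_log2_ratio = numeric())
  }
  final <- fold_change_filter(arch, config$divergence_fold)

  trend_by_comp <- function(cmp) {
    s <- per_comp[[cmp]]$sets
    setNames(as.character(s$trend), s$protein_id)
  }
  ts <- trend_by_comp("synaptic")
  tn <- trend_by_comp("non_synaptic")

  candidates <- cc[match(universe, cc$protein_id), , drop = FALSE] %>%
    mutate(
      trend_synaptic = dplyr::coalesce(unname(ts[.data$protein_id]), "other"),
      trend_non_synaptic = dplyr::coalesce(unname(tn[.data$protein_id]),
                                           "other"),
      in_trend_set = .data$protein_id %in% trend_ids,
      archetypal = .data$protein_id %in% arch$protein_id,
      pass_2fold = .data$protein_id %in% final$protein_id
    ) %>%
    select("protein_id", "trend_synaptic", "trend_non_synaptic",
           "mid_log2_ratio", "old_log2_ratio", "in_trend_set",
           "archetypal", "pass_2fold")

  counts <- tibble(
    stage = c("common_proteins", "retained_synaptic",
              "retained_non_synaptic", "trend_set", "archetypal",
              "final_candidates"),
    n = c(length(universe),
          length(per_comp$synaptic$ids),
          length(per_comp$non_synaptic$ids),
          length(trend_ids),
          nrow(arch),
          nrow(final))
  )

  structure(
    list(
      candidates = candidates,
      counts = counts,
      final_ids = final$protein_id,
      clusters = list(synaptic = per_comp$synaptic$clusters,
                      non_synaptic = per_comp$non_synaptic$clusters),
      trends = list(synaptic = per_comp$synaptic$trends,
                    non_synaptic = per_comp$non_synaptic$trends),
      config = config
    ),
    class = "candidate_funnel"
  )
}

#' @export
print.candidate_funnel <- function(x, ...) {
  cat("<candidate_funnel>\n")
  print(x$counts)
  invisible(x)
}
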