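#' Plot a candidate funnel
#'
#' `type = "funnel"` draws the stage counts as a bar chart;
#' `type = "profiles"` draws the ratio-to-young temporal profiles of the
#' final candidates in both compartments (the published candidate readout),
#' faceted by protein.
#'
#' @param object A [run_funnel()] result.
#' @param type `"funnel"` or `"profiles"`.
#' @param abundance The abundance tibble the funnel was run on (required for
#'   `type = "profiles"`).
#' @param max_proteins Cap on the number of candidate facets drawn.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @method autoplot candidate_funnel
#' @export
autoplot.candidate_funnel <- function(object, type = c("funnel", "profiles"),
                                      abundance = NULL, max_proteins = 12,
                                      ...) {
  type <- match.arg(type)
  if (type == "funnel") {
    d <- object$counts %>%
      filter(.data$stage %in% c("common_proteins", "trend_set",
                                "archetypal", "final_candidates")) %>%
      mutate(stage = factor(.data$stage, levels = .data$stage))
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
        ggplot2::labs(x = NULL, y = "proteins",
                      title = "Candidate prioritisation funnel") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(abundance)) {
    abort("`abundance` is required for type = \"profiles\".")
  }
  ids <- head(object$final_ids, max_proteins)
  if (length(ids) == 0) abort("No final candidates to plot.")
  d <- ratio_to_young(filter(abundance, .data$protein_id %in% ids))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$age, y = .data$ratio,
                 colour = .data$compartment, group = .data$compartment)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~protein_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "expression ratio to young",
                  colour = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot cluster mean temporal profiles by trend class
#'
#' Mean expression per age for each cluster, scaled to its young value and
#' faceted by the assigned trend label.
#'
#' @param profiles A [cluster_profiles()] tibble.
#' @param trends A [cluster_trends()] tibble for the same clustering.
#' @return A [ggplot2::ggplot] object.
#' @export
plot_cluster_trends <- function(profiles, trends) {
  d <- profiles %>%
    group_by(.data$cluster) %>%
    mutate(rel = .data$mean_abundance /
             .data$mean_abundance[.data$age == "young"]) %>%
    ungroup() %>%
    left_join(trends, by = c("cluster", "n_members"))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$age, y = .data$rel,
                 group = .data$cluster, colour = factor(.data$cluster))
  ) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(~trend) +
    ggplot2::labs(x = NULL, y = "mean expression / young") +
    ggplot2::theme_minimal()
}
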