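#' Marker enrichment t-tests between compartments
#'
#' For each marker protein, an unpaired two-tailed two-sample Student
#' t-test (pooled variance by default; Welch behind `welch = TRUE`) of its
#' normalised abundances in one compartment versus the other across all
#' replicate samples. Used as a purity QC: synaptic markers should enrich
#' in synaptic mitochondrial fractions.
#'
#' @param abundance Long-format abundance tibble with both compartments.
#' @param markers Character vector of marker protein ids.
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student test.
#' @return Tibble with `protein_id`, `mean_synaptic`, `mean_non_synaptic`,
#'   `t`, `p`.
#' @export
marker_ttest <- function(abundance, markers, welch = FALSE) {
  abundance <- validate_abundance(abundance)
  missing <- setdiff(markers, unique(abundance$protein_id))
  if (length(missing) > 0) {
    abort(paste0("Marker(s) not found: ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(markers, function(id) {
    x <- abundance$abundance[abundance$protein_id == id &
                               abundance$compartment == "synaptic"]
    y <- abundance$abundance[abundance$protein_id == id &
                               abundance$compartment == "non_synaptic"]
    if (length(x) < 2 || length(y) < 2) {
      abort(paste0("Need >= 2 replicates per compartment for marker ", id))
    }
    if (sd(c(x - mean(x), y - mean(y))) == 0) {
      abort(paste0("Zero pooled variance for marker ", id))
    }
    tt <- t.test(x, y, var.equal = !welch)
    tibble(protein_id = id, mean_synaptic = mean(x),
           mean_non_synaptic = mean(y),
           t = unname(tt$statistic), p = tt$p.value)
  })
}

#' Over-representation of annotation terms in a selection
#'
#' PANTHER-style fold enrichment with a one-sided Fisher exact test
#' (hypergeometric upper tail) and Benjamini-Hochberg FDR across terms.
#' For each term: `observed = |selection ∩ term|`,
#' `expected = |selection| x |term| / |background|`,
#' `fold_enrichment = (observed/|selection|) / (|term|/|background|)`.
#'
#' @param selection Character vector of selected protein ids (must be a
#'   subset of `background`).
#' @param background Character vector of background protein ids.
#' @param annotation Two-column tibble/data frame (`term_id`, `protein_id`)
#'   mapping terms to background members; annotations outside the
#'   background are ignored.
#' @return Tibble with `term_id`, `observed`, `expected`,
#'   `fold_enrichment`, `p`, `fdr`, in term first-appearance order.
#' @export
overrepresentation <- function(selection, background, annotation) {
  selection <- unique(selection)
  background <- unique(background)
  if (length(setdiff(selection, background)) > 0) {
    abort("`selection` must be a subset of `background`.")
  }
  need <- setdiff(c("term_id", "protein_id"), names(annotation))
  if (length(need) > 0) {
    abort(paste0("`annotation` is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  ann <- annotation %>%
    filter(.data$protein_id %in% background) %>%
    distinct(.data$term_id, .data$protein_id)

  n_bg <- length(background)
  n_sel <- length(selection)
  res <- ann %>%
    group_by(.data$term_id) %>%
    summarise(
      term_size = dplyr::n(),
      observed = sum(.data$protein_id %in% selection),
      .groups = "drop"
    ) %>%
    arrange(match(.data$term_id, unique(annotation$term_id))) %>%
    mutate(
      expected = n_sel * .data$term_size / n_bg,
      fold_enrichment = (.data$observed / n_sel) /
        (.data$term_size / n_bg),
      p = phyper(.data$observed - 1, .data$term_size,
                 n_bg - .data$term_size, n_sel, lower.tail = FALSE),
      fdr = bh_fdr(.data$p)
    )
  select(res, "term_id", "term_size", "observed", "expected",
         "fold_enrichment", "p", "fdr")
}

#' Activation z-score of an upstream regulator
#'
#' Net direction-consistency of observed expression changes with a signed
#' regulator-to-target network:
#' `z = (n_consistent - n_inconsistent) / sqrt(n_consistent + n_inconsistent)`.
#' Positive z predicts activation, negative z predicts inhibition; a
#' regulator with no observed targets gets `z = NA`. Targets absent from
#' `observed` are ignored.
#'
#' @param expectations Tibble with `regulator`, `target`,
#'   `expected_direction` (+1 or -1: the sign of the target change expected
#'   under regulator activation).
#' @param observed Tibble with `target` and `direction` (+1 or -1).
#' @return Tibble with `regulator`, `n_consistent`, `n_inconsistent`, `z`.
#' @export
#' @examples
#' expectations <- tibble::tibble(
#'   regulator = "R1", target = paste0("T", 1:9), expected_direction = 1
#' )
#' observed <- tibble::tibble(target = paste0("T", 1:9), direction = 1)
#' activation_z(expectations, observed)  # z = 3
activation_z <- function(expectations, observed) {
  if (!all(expectations$expected_direction %in% c(-1, 1))) {
    abort("`expected_direction` must be +1 or -1.")
  }
  if (!all(observed$direction %in% c(-1, 1))) {
    abort("`direction` must be +1 or -1.")
  }
  expectations %>%
    dplyr::inner_join(distinct(observed, .data$target, .data$direction),
                      by = "target") %>%
    group_by(.data$regulator) %>%
    summarise(
      n_consistent = sum(.data$expected_direction == .data$direction),
      n_inconsistent = sum(.data$expected_direction != .data$direction),
      .groups = "drop"
    ) %>%
    dplyr::right_join(distinct(expectations, .data$regulator),
                      by = "regulator") %>%
    mutate(
      n_consistent = dplyr::coalesce(.data$n_consistent, 0L),
      n_inconsistent = dplyr::coalesce(.data$n_inconsistent, 0L),
      z = ifelse(.data$n_consistent + .data$n_inconsistent == 0,
                 NA_real_,
                 (.data$n_consistent - .data$n_inconsistent) /
                   sqrt(.data$n_consistent + .data$n_inconsistent))
    )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
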