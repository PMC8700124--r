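#' Simulation configuration
#'
#' Describes a synthetic two-compartment (synaptic / non-synaptic), three-age
#' (young / mid / old) proteomic timecourse with planted temporal trend
#' classes. The defaults emulate the study design the package targets: three
#' technical replicates per age group, multiplicative log-normal noise, and a
#' mixture of flat, steadily changing, late-changing and old-age
#' compartment-divergent proteins.
#'
#' @param n_proteins Number of simulated proteins.
#' @param replicates_per_group Replicates per (compartment, age) cell.
#' @param class_fractions Named numeric vector of proportions over the trend
#'   classes `flat`, `steady_up`, `steady_down`, `late_up`, `late_down`,
#'   `divergent_old`; must be non-negative and sum to 1.
#' @param effect_size Fold change applied per planted step for steady/late
#'   classes (dimensionless ratio > 1).
#' @param divergent_fold Old-age synaptic vs non-synaptic fold for the
#'   `divergent_old` class (> 1). The direction (up vs down at old age)
#'   alternates deterministically by protein index within the class.
#' @param noise_sd Standard deviation of the log-scale multiplicative noise.
#' @param baseline_range Length-2 numeric giving the bounds of the (log-
#'   uniform) baseline abundance distribution.
#' @param frac_single_peptide Proportion of proteins assigned
#'   `unique_peptides = 1` (to exercise the protein-level peptide filter);
#'   the remainder draw uniformly from 2--20.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_proteome()]
#' @export
#' @examples
#' sim_config(n_proteins = 100, seed = 1)
sim_config <- function(n_proteins = 1000,
                       replicates_per_group = 3,
                       class_fractions = c(
                         flat = 0.40, steady_up = 0.12, steady_down = 0.12,
                         late_up = 0.09, late_down = 0.09, divergent_old = 0.18
                       ),
                       effect_size = 1.5,
                       divergent_fold = 2.5,
                       noise_sd = 0.1,
                       baseline_range = c(1e4, 1e7),
                       frac_single_peptide = 0.05,
                       seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1 ||
      n_proteins < 1 || n_proteins != floor(n_proteins)) {
    abort("`n_proteins` must be a positive integer.")
  }
  if (replicates_per_group < 1) abort("`replicates_per_group` must be >= 1.")
  cf <- class_fractions[trend_classes()]
  if (anyNA(cf)) {
    abort(paste0(
      "`class_fractions` must name all of: ",
      paste(trend_classes(), collapse = ", ")
    ))
  }
  if (any(cf < 0)) abort("`class_fractions` must be non-negative.")
  if (abs(sum(cf) - 1) > 1e-9) abort("`class_fractions` must sum to 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (effect_size <= 1) abort("`effect_size` must be > 1.")
  if (divergent_fold <= 1) abort("`divergent_fold` must be > 1.")
  if (length(baseline_range) != 2 || any(baseline_range <= 0) ||
      baseline_range[1] > baseline_range[2]) {
    abort("`baseline_range` must be positive and increasing.")
  }
  if (frac_single_peptide < 0 || frac_single_peptide > 1) {
    abort("`frac_single_peptide` must be in [0, 1].")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      replicates_per_group = as.integer(replicates_per_group),
      class_fractions = cf,
      effect_size = effect_size,
      divergent_fold = divergent_fold,
      noise_sd = noise_sd,
      baseline_range = as.numeric(baseline_range),
      frac_single_peptide = frac_single_peptide,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

trend_classes <- function() {
  c("flat", "steady_up", "steady_down", "late_up", "late_down", "divergent_old")
}

age_levels <- function() c("young", "mid", "old")

compartment_levels <- function() c("synaptic", "non_synaptic")

#' Pipeline configuration
#'
#' Houses every numeric threshold of the analysis: the Pearson edge threshold
#' and MCL parameters of the network stage, the ANOVA/power/fold-change
#' feature filter and the unique-peptide protein filter, the trend-call
#' epsilon, and the concordance/divergence thresholds of the candidate
#' funnel.
#'
#' @param pearson_threshold Minimum (signed) Pearson r for a graph edge.
#' @param mcl_inflation MCL inflation (elementwise power; > 1).
#' @param mcl_expansion MCL expansion (matrix power; integer >= 2).
#' @param mcl_prune Entries below this are zeroed each MCL iteration.
#' @param mcl_tol Convergence tolerance on the max absolute change per cycle.
#' @param alpha Significance level for the ANOVA p-value filters.
#' @param power_min Minimum post-hoc ANOVA power retained.
#' @param fc_min Minimum max/min group-mean fold change retained.
#' @param min_unique_peptides Minimum unique peptides per retained protein.
#' @param trend_epsilon Relative-change threshold for trend classification
#'   (a step counts as up when the ratio is >= 1 + epsilon).
#' @param concord_tau Maximum |log2 synaptic/non-synaptic ratio| at mid-age
#'   for cross-compartment concordance (young is 1:1 by construction of the
#'   ratio-to-young profiles).
#' @param divergence_fold Minimum old-age cross-compartment fold change for
#'   the final candidate filter.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @export
#' @examples
#' pipeline_config()
pipeline_config <- function(pearson_threshold = 0.96,
                            mcl_inflation = 2.2,
                            mcl_expansion = 2L,
                            mcl_prune = 1e-6,
                            mcl_tol = 1e-8,
                            alpha = 0.05,
                            power_min = 0.8,
                            fc_min = 1.2,
                            min_unique_peptides = 2L,
                            trend_epsilon = 0.2,
                            concord_tau = log2(1.5),
                            divergence_fold = 2.0) {
  if (pearson_threshold <= 0 || pearson_threshold >= 1) {
    abort("`pearson_threshold` must be in (0, 1).")
  }
  if (mcl_inflation <= 1) abort("`mcl_inflation` must be > 1.")
  if (mcl_expansion < 2 || mcl_expansion != floor(mcl_expansion)) {
    abort("`mcl_expansion` must be an integer >= 2.")
  }
  if (mcl_prune < 0) abort("`mcl_prune` must be >= 0.")
  if (mcl_tol <= 0) abort("`mcl_tol` must be > 0.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (power_min < 0 || power_min > 1) abort("`power_min` must be in [0, 1].")
  if (fc_min < 1) abort("`fc_min` must be >= 1.")
  if (min_unique_peptides < 1) abort("`min_unique_peptides` must be >= 1.")
  if (trend_epsilon <= 0) abort("`trend_epsilon` must be > 0.")
  if (concord_tau <= 0) abort("`concord_tau` must be > 0.")
  if (divergence_fold < 1) abort("`divergence_fold` must be >= 1.")
  structure(
    list(
      pearson_threshold = pearson_threshold,
      mcl_inflation = mcl_inflation,
      mcl_expansion = as.integer(mcl_expansion),
      mcl_prune = mcl_prune,
      mcl_tol = mcl_tol,
      alpha = alpha,
      power_min = power_min,
      fc_min = fc_min,
      min_unique_peptides = as.integer(min_unique_peptides),
      trend_epsilon = trend_epsilon,
      concord_tau = concord_tau,
      divergence_fold = divergence_fold
    ),
    class = "pipeline_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  proteins:", x$n_proteins,
      " replicates/group:", x$replicates_per_group,
      " seed:", x$seed, "\n")
  cat("  effect_size:", x$effect_size,
      " divergent_fold:", x$divergent_fold,
      " noise_sd:", x$noise_sd, "\n")
  cat("  class fractions:",
      paste(names(x$class_fractions), x$class_fractions,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}
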