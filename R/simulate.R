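#' Simulate a two-compartment proteomic ageing timecourse
#'
#' Generates a long-format abundance table with planted, labelled temporal
#' structure: proteins are assigned to trend classes (flat, steady up/down,
#' late-stage up/down, or old-age synaptic-divergent), given a log-uniform
#' baseline abundance, and perturbed by multiplicative log-normal noise.
#'
#' Planted group means per class (e = `effect_size`, f = `divergent_fold`):
#' * `flat` — equal means across ages in both compartments;
#' * `steady_up` / `steady_down` — the mean is multiplied (divided) by `e`
#'   at each successive age in both compartments;
#' * `late_up` / `late_down` — young and mid equal, old = mid x e (or / e)
#'   in both compartments;
#' * `divergent_old` — flat in non-synaptic mitochondria; in synaptic
#'   mitochondria flat from young to mid, then old = mid x f or mid / f,
#'   the sign alternating deterministically by protein index.
#'
#' @param config A [sim_config()].
#' @return A list of class `proteome_sim` with elements
#'   * `abundance` — tibble with one row per (protein, sample):
#'     `protein_id`, `sample_id`, `compartment`, `age` (ordered factor),
#'     `replicate`, `abundance`, `unique_peptides`;
#'   * `truth` — tibble with `protein_id`, `class`, `compartment` (where the
#'     planted effect acts: `"both"`, `"synaptic"`, or `"none"` for flat),
#'     and `direction` (`"up"`, `"down"`, `"none"`).
#' @export
#' @examples
#' sim <- simulate_proteome(sim_config(n_proteins = 50, seed = 3))
#' head(sim$abundance)
#' dplyr::count(sim$truth, class)
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_proteome_impl(config))
}

simulate_proteome_impl <- function(config) {
  n <- config$n_proteins
  reps <- config$replicates_per_group
  classes <- allocate_classes(config$class_fractions, n)
  protein_id <- sprintf("P%05d", seq_len(n))

  baseline <- 10^runif(n,
                       log10(config$baseline_range[1]),
                       log10(config$baseline_range[2]))

  # divergence sign alternates by index within the divergent class
  direction <- rep("none", n)
  direction[classes %in% c("steady_up", "late_up")] <- "up"
  direction[classes %in% c("steady_down", "late_down")] <- "down"
  div_idx <- which(classes == "divergent_old")
  direction[div_idx] <- ifelse(seq_along(div_idx) %% 2 == 1, "up", "down")

  n_single <- round(config$frac_single_peptide * n)
  unique_peptides <- sample(2:20, n, replace = TRUE)
  if (n_single > 0) {
    unique_peptides[sample.int(n, n_single)] <- 1L
  }

  samples <- tidyr::expand_grid(
    compartment = compartment_levels(),
    age = age_levels(),
    replicate = seq_len(reps)
  ) %>%
    mutate(sample_id = paste(.data$compartment, .data$age, .data$replicate,
                             sep = "_"))

  # class multipliers per (compartment, age)
  mult <- planted_multiplier(
    class = rep(classes, each = nrow(samples)),
    direction = rep(direction, each = nrow(samples)),
    compartment = rep(samples$compartment, times = n),
    age = rep(samples$age, times = n),
    effect_size = config$effect_size,
    divergent_fold = config$divergent_fold
  )

  abundance <- tibble(
    protein_id = rep(protein_id, each = nrow(samples)),
    sample_id = rep(samples$sample_id, times = n),
    compartment = factor(rep(samples$compartment, times = n),
                         levels = compartment_levels()),
    age = factor(rep(samples$age, times = n),
                 levels = age_levels(), ordered = TRUE),
    replicate = rep(samples$replicate, times = n),
    abundance = rep(baseline, each = nrow(samples)) * mult *
      exp(rnorm(n * nrow(samples), mean = 0, sd = config$noise_sd)),
    unique_peptides = rep(as.integer(unique_peptides), each = nrow(samples))
  )

  truth <- tibble(
    protein_id = protein_id,
    class = classes,
    compartment = dplyr::case_when(
      classes == "flat" ~ "none",
      classes == "divergent_old" ~ "synaptic",
      TRUE ~ "both"
    ),
    direction = direction
  )

  structure(list(abundance = abundance, truth = truth, config = config),
            class = "proteome_sim")
}

# Deterministic largest-remainder allocation of class counts, assigned in
# protein order so identical configs give identical labels.
allocate_classes <- function(fractions, n) {
  ideal <- fractions * n
  counts <- floor(ideal)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(ideal - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(fractions), times = counts)
}

planted_multiplier <- function(class, direction, compartment, age,
                               effect_size, divergent_fold) {
  e <- ifelse(direction == "down", 1 / effect_size, effect_size)
  f <- ifelse(direction == "down", 1 / divergent_fold, divergent_fold)
  step <- ifelse(age == "young", 0L, ifelse(age == "mid", 1L, 2L))
  mult <- rep(1, length(class))

  steady <- class %in% c("steady_up", "steady_down")
  mult[steady] <- e[steady]^step[steady]

  late <- class %in% c("late_up", "late_down")
  mult[late] <- ifelse(age[late] == "old", e[late], 1)

  div <- class == "divergent_old" & compartment == "synaptic" & age == "old"
  mult[div] <- f[div]

  mult
}

#' @export
print.proteome_sim <- function(x, ...) {
  cat("<proteome_sim>", x$config$n_proteins, "proteins x",
      dplyr::n_distinct(x$abundance$sample_id), "samples\n")
  print(count(x$truth, .data$class))
  invisible(x)
}

#' Write a simulated dataset to delimited text
#'
#' Writes the three TSV files that [read_abundance()] round-trips: an
#' abundance matrix (`abundance.tsv`; rows = proteins, columns = samples,
#' plus a `unique_peptides` metadata column), sample metadata
#' (`samples.tsv`: sample_id, compartment, age, replicate) and the planted
#' ground truth (`truth.tsv`).
#'
#' @param sim A `proteome_sim` from [simulate_proteome()], or a long
#'   abundance tibble of the same shape (in which case no truth file is
#'   written unless `truth` is supplied).
#' @param dir Output directory (created if needed).
#' @param truth Optional truth tibble when `sim` is a plain abundance table.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_proteome_dataset <- function(sim, dir, truth = NULL) {
  if (inherits(sim, "proteome_sim")) {
    abundance <- sim$abundance
    truth <- sim$truth
  } else {
    abundance <- validate_abundance(sim)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  samples <- distinct(abundance, .data$sample_id, .data$compartment,
                      .data$age, .data$replicate)
  wide <- abundance %>%
    select("protein_id", "unique_peptides", "sample_id", "abundance") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "abundance")
  # preserve input protein order
  wide <- wide[match(unique(abundance$protein_id), wide$protein_id), ,
               drop = FALSE]

  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    samples = file.path(dir, "samples.tsv")
  )
  readr::write_tsv(wide, paths[["abundance"]])
  readr::write_tsv(samples, paths[["samples"]])
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, paths[["truth"]])
  }
  invisible(paths)
}
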