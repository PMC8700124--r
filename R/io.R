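#' Read an abundance matrix and its sample metadata
#'
#' Parses the package's delimited dialect (tab-separated, UTF-8, `.` decimal,
#' mandatory header, `#` comment lines ignored): an abundance matrix TSV with
#' a `protein_id` column, an optional `unique_peptides` column, and one
#' column per sample; plus a sample-metadata TSV with columns `sample_id`,
#' `compartment` (`synaptic` / `non_synaptic`), `age` (`young` / `mid` /
#' `old`) and `replicate`. Sample order follows the metadata file.
#'
#' @param matrix_path Path to the abundance matrix TSV.
#' @param samples_path Path to the sample metadata TSV.
#' @return A long-format abundance tibble (see [simulate_proteome()] for the
#'   column contract) satisfying the abundance invariants: strictly positive
#'   finite values, unique (protein, sample) pairs, unique sample ids.
#' @export
read_abundance <- function(matrix_path, samples_path) {
  mat <- readr::read_tsv(matrix_path, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(samples_path, comment = "#",
                          show_col_types = FALSE, progress = FALSE)

  need <- setdiff(c("sample_id", "compartment", "age", "replicate"),
                  names(meta))
  if (length(need) > 0) {
    abort(paste0("Sample metadata is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    abort(paste0("Duplicated sample_id in metadata: ",
                 paste(dup, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(meta$compartment), compartment_levels())
  if (length(bad_comp) > 0) {
    abort(paste0("Unknown compartment token(s): ",
                 paste(bad_comp, collapse = ", ")))
  }
  bad_age <- setdiff(unique(meta$age), age_levels())
  if (length(bad_age) > 0) {
    abort(paste0("Unknown age token(s): ", paste(bad_age, collapse = ", ")))
  }
  if (!"protein_id" %in% names(mat)) {
    abort("Abundance matrix is missing the protein_id column.")
  }
  missing_samples <- setdiff(meta$sample_id, names(mat))
  if (length(missing_samples) > 0) {
    abort(paste0("Abundance matrix is missing sample column(s): ",
                 paste(missing_samples, collapse = ", ")))
  }
  if (anyDuplicated(mat$protein_id)) {
    abort("Duplicated protein_id in abundance matrix.")
  }

  if (!"unique_peptides" %in% names(mat)) mat$unique_peptides <- NA_integer_

  long <- mat %>%
    select("protein_id", "unique_peptides", dplyr::all_of(meta$sample_id)) %>%
    tidyr::pivot_longer(cols = dplyr::all_of(meta$sample_id),
                        names_to = "sample_id", values_to = "abundance") %>%
    left_join(meta, by = "sample_id") %>%
    mutate(
      compartment = factor(.data$compartment, levels = compartment_levels()),
      age = factor(.data$age, levels = age_levels(), ordered = TRUE),
      replicate = as.integer(.data$replicate),
      unique_peptides = as.integer(.data$unique_peptides)
    ) %>%
    select("protein_id", "sample_id", "compartment", "age", "replicate",
           "abundance", "unique_peptides")

  validate_abundance(long)
}

#' Validate a long-format abundance table
#'
#' Checks the invariants every stage of the pipeline relies on: required
#' columns, strictly positive finite abundances (errors name the offending
#' protein/sample cell), and unique (protein, sample) pairs.
#'
#' @param abundance A long-format abundance tibble.
#' @return The validated tibble (with `compartment`/`age` coerced to their
#'   canonical factor encodings), invisibly usable in a pipe.
#' @export
validate_abundance <- function(abundance) {
  need <- setdiff(c("protein_id", "sample_id", "compartment", "age",
                    "replicate", "abundance"),
                  names(abundance))
  if (length(need) > 0) {
    abort(paste0("Abundance table is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  bad <- !is.finite(abundance$abundance) | abundance$abundance <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Abundance must be positive and finite; offending value %s at protein %s, sample %s (%d cell(s) total).",
      format(abundance$abundance[i]), abundance$protein_id[i],
      abundance$sample_id[i], sum(bad)
    ))
  }
  if (anyDuplicated(abundance[c("protein_id", "sample_id")])) {
    abort("Duplicated (protein_id, sample_id) pairs in abundance table.")
  }
  abundance %>%
    mutate(
      compartment = factor(as.character(.data$compartment),
                           levels = compartment_levels()),
      age = factor(as.character(.data$age),
                   levels = age_levels(), ordered = TRUE)
    )
}

#' Per-protein group means over (compartment, age) cells
#'
#' Averages replicate abundances within each (compartment, age) cell,
#' preserving the input protein order.
#'
#' @param abundance A long-format abundance tibble.
#' @return Tibble with `protein_id`, `compartment`, `age`, `mean_abundance`,
#'   `n_replicates`.
#' @export
group_means <- function(abundance) {
  abundance <- validate_abundance(abundance)
  order_ids <- unique(abundance$protein_id)
  abundance %>%
    group_by(.data$protein_id, .data$compartment, .data$age) %>%
    summarise(mean_abundance = mean(.data$abundance),
              n_replicates = dplyr::n(), .groups = "drop") %>%
    arrange(match(.data$protein_id, order_ids), .data$compartment, .data$age)
}

# proteins x samples numeric matrix for one compartment (or all samples),
# with columns ordered by (age, replicate); rows keep input protein order.
abundance_wide <- function(abundance, compartment = NULL) {
  if (!is.null(compartment)) {
    abundance <- filter(abundance, .data$compartment == !!compartment)
    if (nrow(abundance) == 0) {
      abort(paste0("No samples in compartment: ", compartment))
    }
  }
  samples <- distinct(abundance, .data$sample_id, .data$compartment,
                      .data$age, .data$replicate) %>%
    arrange(.data$compartment, .data$age, .data$replicate)
  ids <- unique(abundance$protein_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = nrow(samples),
              dimnames = list(ids, samples$sample_id))
  m[cbind(match(abundance$protein_id, ids),
          match(abundance$sample_id, samples$sample_id))] <- abundance$abundance
  list(values = m, samples = samples)
}
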