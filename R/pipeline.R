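#' Run the full analysis and write its artifacts
#'
#' Orchestrates the whole pipeline — optional simulation, per-protein
#' filtering statistics, sample and protein correlation graphs, MCL
#' clustering, trend classification, the subtractive candidate funnel and
#' the >20%-altered census — and writes every artifact plus a JSON run
#' manifest to `out_dir`. Identical inputs and configuration give
#' byte-identical TSV outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param abundance Long-format abundance tibble; omit to simulate one from
#'   `sim` instead.
#' @param sim A [sim_config()] used when `abundance` is `NULL`.
#' @param config A [pipeline_config()].
#' @param input_paths Optional named character vector of input file paths,
#'   recorded in the manifest with their MD5 digests.
#' @return Invisibly, a list with the `candidate_funnel`, the manifest, and
#'   the paths written.
#' @export
run_pipeline <- function(out_dir,
                         abundance = NULL,
                         sim = sim_config(),
                         config = pipeline_config(),
                         input_paths = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  simulated <- is.null(abundance)
  truth <- NULL
  if (simulated) {
    s <- simulate_proteome(sim)
    abundance <- s$abundance
    truth <- s$truth
    paths <- c(paths, write_proteome_dataset(s, out_dir))
  } else {
    abundance <- validate_abundance(abundance)
  }

  stats <- flag_filters(feature_stats(abundance, config), config)
  p_stats <- file.path(out_dir, "feature_stats.tsv")
  readr::write_tsv(stats, p_stats)
  paths <- c(paths, feature_stats = p_stats)

  sample_graphs <- purrr::map(
    setNames(compartment_levels(), compartment_levels()),
    function(cmp) build_sample_graph(abundance, config, compartment = cmp)
  )
  for (cmp in compartment_levels()) {
    p <- file.path(out_dir, paste0("sample_graph_", cmp, ".graphml"))
    write_graphml(sample_graphs[[cmp]], p)
    paths <- c(paths, setNames(p, paste0("sample_graph_", cmp)))
  }

  funnel <- run_funnel(abundance, config)
  p_cand <- file.path(out_dir, "candidates.tsv")
  readr::write_tsv(funnel$candidates, p_cand)
  paths <- c(paths, candidates = p_cand)

  for (cmp in compartment_levels()) {
    cl <- funnel$clusters[[cmp]]
    if (is.null(cl)) next
    p <- file.path(out_dir, paste0("clusters_", cmp, ".tsv"))
    readr::write_tsv(
      left_join(tidy(cl), funnel$trends[[cmp]], by = "cluster"), p
    )
    paths <- c(paths, setNames(p, paste0("clusters_", cmp)))
  }

  altered <- count_altered(abundance)
  summary <- list(
    funnel = as.list(setNames(funnel$counts$n, funnel$counts$stage)),
    n_altered = as.list(setNames(altered$n_altered,
                                 as.character(altered$compartment))),
    sample_graph_components = purrr::map(sample_graphs, n_components)
  )
  p_summary <- file.path(out_dir, "funnel_summary.json")
  jsonlite::write_json(summary, p_summary, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, summary = p_summary)

  manifest <- list(
    package = "mitofunnel",
    version = as.character(utils::packageVersion("mitofunnel")),
    simulated = simulated,
    seed = if (simulated) sim$seed else NULL,
    config = unclass(config),
    sim_config = if (simulated) {
      c(unclass(sim)[setdiff(names(sim), "class_fractions")],
        list(class_fractions = as.list(sim$class_fractions)))
    } else NULL,
    inputs = if (!is.null(input_paths)) {
      as.list(tools::md5sum(input_paths))
    } else NULL,
    counts = as.list(setNames(funnel$counts$n, funnel$counts$stage)),
    n_samples = dplyr::n_distinct(abundance$sample_id),
    n_proteins = dplyr::n_distinct(abundance$protein_id)
  )
  p_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, manifest = p_manifest)

  invisible(list(funnel = funnel, truth = truth, manifest = manifest,
                 paths = paths))
}
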