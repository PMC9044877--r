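# Canned end-to-end workflow on generated fixtures: simulate, build a grid
# of definitions, evaluate them against the planted TF annotations, select
# the top set and compare everything to the baseline locus definitions.

#' Run the full evaluation workflow on a synthetic regulome
#'
#' Generates a toy genome and regulome from `spec`, enumerates definition
#' configurations over a subset of the generated sources and link tracks,
#' assembles every configuration, evaluates all of them (plus the
#' nearest-TSS and beyond-5kb baselines) by mean F1 against the planted TF
#' annotations, selects the top set, and compares each definition to the
#' distal baseline.  All outputs and a reproducibility manifest are
#' written under `out_dir`.
#'
#' @param spec `SimulationSpec`.
#' @param out_dir output directory (created).
#' @param n_sources_use,n_links_use number of enhancer sources and
#'   non-loop link tracks entering the enumeration (kept small by default:
#'   the grid grows as `(2^s-1)((2^k-1)(1+v)+v) * 4`).
#' @param loop_variants_use number of loop variants in the enumeration.
#' @param plan `NegativeSamplingPlan`.
#' @param gse_spec `GSEModelSpec`.
#' @return list with `ranking`, `top_set`, `baseline_comparison`, and the
#'   paths of the written artifacts.
#' @export
run_full_evaluation <- function(spec, out_dir,
                                n_sources_use = 2L, n_links_use = 2L,
                                loop_variants_use = 1L,
                                plan = negative_sampling_plan(
                                  rng_seed = spec$seed),
                                gse_spec = gse_model_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- make_toy_genome(spec)
  regulome <- make_toy_regulome(spec, registry)
  src_names <- utils::head(names(regulome$sources), n_sources_use)
  nonloop <- utils::head(c("pairsA", "pairsB", "chia"), n_links_use)
  configs <- enumerate_definitions(src_names, nonloop,
                                   loop_variants = loop_variants_use)
  names(configs) <- vapply(configs, config_id, "")
  defs <- lapply(configs, assemble_entdef, sources = regulome$sources,
                 evidence = regulome$evidence, registry = registry)
  baselines <- list(
    nearest_tss = build_locusdef("nearest_tss", registry),
    beyond_5kb = build_locusdef("beyond_5kb", registry))
  peaksets <- lapply(names(regulome$tf_terms), function(tf) {
    make_tf_peaks(spec, registry, regulome, tf)
  })
  tf_of <- stats::setNames(names(regulome$tf_terms),
                           names(regulome$tf_terms))
  results <- evaluate_definitions(
    c(defs, baselines), peaksets, tf_of, regulome$sets,
    regulome$annotations, registry, spec = gse_spec, plan = plan)
  top <- select_top_set(results)
  cmp <- compare_to_baseline(results, "beyond_5kb")
  ranking_path <- file.path(out_dir, "ranking.tsv")
  utils::write.table(results$ranking, ranking_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cmp_path <- file.path(out_dir, "baseline_comparison.tsv")
  utils::write.table(cmp, cmp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(seed = spec$seed, n_definitions = length(defs),
                   n_tfs = spec$n_tfs,
                   plan = unclass(plan), gse_method = gse_spec$method,
                   top_set = top$top_set,
                   cutoff_rank = top$cutoff_rank)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  list(ranking = results$ranking, top_set = top, baseline_comparison = cmp,
       results = results,
       paths = c(ranking = ranking_path, comparison = cmp_path))
}
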