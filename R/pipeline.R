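#' Run the whole analysis end-to-end on synthetic data
#'
#' Simulate -> write inputs -> preprocess (quantile normalize, log2,
#' split by condition) -> SAM over every trait x condition -> GO singular
#' enrichment of the pooled significant genes -> chromosome tally and
#' interaction subnetwork. Every output is a TSV under `out_dir`; with a
#' fixed master seed two runs are byte-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [sim_config()]; its master seed drives everything,
#'   including the permutation substream.
#' @param B Number of permutations per trait (default 100).
#' @param traits Traits to analyze (default: the config's trait list).
#' @param max_fdr_percent,min_abs_d Selection thresholds (defaults 5, 2).
#' @param sea_fdr SEA significance threshold (default 0.05).
#' @param n_edges Interactome size (default `4 * n_probes`).
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `significant`, `sea`, `subnetwork`, `chromosomes`, `truth`).
#' @export
run_pipeline <- function(out_dir, config = sim_config(), B = 100L,
                         traits = NULL, max_fdr_percent = 5, min_abs_d = 2,
                         sea_fdr = 0.05, n_edges = NULL, quiet = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- if (quiet) suppressMessages else identity
  run({
  sim <- generate_dataset(config)
  write_expression_matrix(sim$expression,
                          file.path(out_dir, "expression.tsv"),
                          file.path(out_dir, "sample_sheet.tsv"))
  write_trait_table(sim$traits, file.path(out_dir, "traits.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- generate_go_annotation(sim$truth,
                                rownames(sim$expression$values),
                                seed = config$seed)
  utils::write.table(as.data.frame(ann),
                     file.path(out_dir, "go_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hub <- sim$truth$probe_id[[1L]]
  edges <- generate_interactome(rownames(sim$expression$values),
                                n_edges = n_edges %||%
                                  (4L * config$n_probes),
                                hub = hub, hub_degree = 20L,
                                seed = config$seed)
  utils::write.table(as.data.frame(edges),
                     file.path(out_dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  norm <- log2_transform(quantile_normalize(sim$expression),
                         pseudocount = 0)
  use_traits <- traits %||% names(sim$traits)
  all_res <- run_all_traits(norm, sim$traits[, use_traits, drop = FALSE],
                            B = B,
                            seed = derive_seed(config$seed, "permutation"),
                            max_fdr_percent = max_fdr_percent,
                            min_abs_d = min_abs_d)
  utils::write.table(all_res$counts, file.path(out_dir, "sam_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_tables <- lapply(all_res$results, `[[`, "significant")
  pooled <- sort(unique(unlist(lapply(sig_tables, `[[`, "probe_id"))))
  for (key in names(sig_tables))
    write_significant_table(sig_tables[[key]],
                            file.path(out_dir,
                                      paste0("significant_", key, ".tsv")))

  sea <- if (length(pooled))
    run_sea(pooled, ann, background = rownames(sim$expression$values),
            alpha_fdr = sea_fdr) else NULL
  if (!is.null(sea))
    utils::write.table(as.data.frame(sea), file.path(out_dir, "sea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  chrom <- chromosome_distribution(pooled)
  utils::write.table(data.frame(chromosome = names(chrom),
                                n_genes = as.integer(chrom)),
                     file.path(out_dir, "chromosome_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  subnet <- induce_subnetwork(pooled, edges)
  write_subnetwork(subnet, file.path(out_dir, "subnetwork.tsv"))
  })
  invisible(list(counts = all_res$counts, significant = sig_tables,
                 sea = sea, subnetwork = subnet, chromosomes = chrom,
                 truth = sim$truth))
}
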