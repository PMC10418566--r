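#' Run the full methylation-network pipeline
#'
#' Chains probe clustering, beta averaging, candidate-network construction,
#' per-context elastic-net fitting, consensus aggregation, association
#' scoring, distance detrending, regulatory-potential summation and hub
#' calling. With `out_dir` set, the main tables are written as TSVs with a
#' fixed column order and formatting, so repeated runs with the same seed
#' produce byte-identical files.
#'
#' @param genes Gene tibble ([read_gene_annotation()] or fixture).
#' @param probes Probe tibble.
#' @param methylation Probe-by-sample beta matrix.
#' @param expression Gene-by-sample log-normalized matrix.
#' @param samples Sample tibble.
#' @param diameter Probe-cluster diameter in bp (default 200).
#' @param radius Candidate window half-width in bp (default 1e6).
#' @param seed Seed for cross-validation folds.
#' @param out_dir Optional output directory for TSVs.
#' @param ... Passed to [fit_contexts()].
#' @return List with `clusters`, `cluster_betas`, `network`,
#'   `context_networks`, `consensus`, `scored` (with `adjusted_score`),
#'   `trend`, `potentials` (with hub flags).
#' @export
methnet_pipeline <- function(genes, probes, methylation, expression, samples,
                             diameter = 200, radius = 1e6, seed = 1,
                             out_dir = NULL, ...) {
  clusters <- cluster_probes(probes, diameter = diameter)
  cluster_betas <- average_cluster_beta(methylation, clusters)
  network <- build_candidate_network(genes, clusters, radius = radius)
  context_networks <- fit_contexts(expression, cluster_betas, network,
                                   samples, seed = seed, ...)
  consensus <- build_consensus(context_networks, network)
  scored <- association_score(consensus, network)
  trend <- fit_distance_trend(scored)
  scored <- adjust_scores(scored, trend)
  potentials <- regulatory_potential(scored, clusters = clusters,
                                     cluster_betas = cluster_betas) |>
    call_hubs()
  res <- list(clusters = clusters, cluster_betas = cluster_betas,
              network = network, context_networks = context_networks,
              consensus = consensus, scored = scored, trend = trend,
              potentials = potentials)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write the pipeline's main tables as TSVs
#'
#' @param res Result list from [methnet_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$network$edges, file.path(out_dir, "candidate_network.tsv"),
                   progress = FALSE)
  models <- map(res$context_networks, function(cn) {
    mutate(cn$models, context = cn$context, .before = 1)
  }) |> list_rbind()
  readr::write_tsv(models, file.path(out_dir, "models.tsv"), progress = FALSE)
  readr::write_tsv(select(res$scored, "gene_id", "cluster_id", "coefficient",
                          "robustness", "sign_class", "d", "score",
                          "adjusted_score"),
                   file.path(out_dir, "consensus.tsv"), progress = FALSE)
  pots <- res$potentials |>
    select("cluster_id", "potential", "methylation_variance", "is_hub")
  readr::write_tsv(pots, file.path(out_dir, "potentials.tsv"), progress = FALSE)
  hubs <- res$potentials |>
    filter(.data$is_hub) |>
    inner_join(select(res$clusters, "cluster_id", "chrom", "start", "end"),
               by = "cluster_id") |>
    select("chrom", "start", "end", "cluster_id")
  readr::write_tsv(hubs, file.path(out_dir, "hubs.bed"), col_names = FALSE,
                   progress = FALSE)
  invisible(out_dir)
}
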