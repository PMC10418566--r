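#' Sorted-potential curve with the hub threshold
#'
#' @param potentials Result of [call_hubs()].
#' @return A ggplot.
#' @export
plot_potential_curve <- function(potentials) {
  df <- potentials |>
    arrange(desc(.data$potential)) |>
    mutate(rank = row_number())
  thr <- attr(potentials, "elbow_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$potential)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_hub), size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = "regulatory potential",
                  colour = "hub",
                  title = sprintf("%d hubs at threshold %.3g",
                                  sum(df$is_hub), thr)) +
    ggplot2::theme_minimal()
}

#' Distance-rank profile of mean coefficient and association probability
#'
#' @param profile Tibble from [distance_rank_profile()].
#' @return A ggplot (ranked positions on x, the two metrics facetted).
#' @export
plot_distance_profile <- function(profile) {
  df <- profile |>
    filter(.data$region != "gene_body") |>
    pivot_longer(c("mean_coefficient", "association_probability"),
                 names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   colour = .data$island)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "distance rank (negative = upstream)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Loop-overlap ratio by score bin
#'
#' @param bins Tibble from [score_bin_enrichment()].
#' @return A ggplot.
#' @export
plot_score_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = factor(.data$bin), y = .data$ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ratio - .data$se,
                                        ymax = .data$ratio + .data$se),
                           width = 0.3) +
    ggplot2::labs(x = "association score bin", y = "loop overlap ratio") +
    ggplot2::theme_minimal()
}

#' ROC curves of binned potential predicting multi-loop bins
#'
#' @param aucs Tibble from [hub_auc()].
#' @return A ggplot.
#' @export
plot_hub_roc <- function(aucs) {
  curves <- aucs |>
    filter(!is.na(.data$auc)) |>
    mutate(label = sprintf(">= %d loops (AUC %.2f)", .data$threshold, .data$auc)) |>
    select("label", "curve") |>
    unnest("curve")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "hub definition") +
    ggplot2::theme_minimal()
}
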