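#' Call chromatin-loop overlap for scored associations
#'
#' An association overlaps a loop when one anchor intersects the cluster
#' span and the other anchor intersects the gene's promoter interval
#' (TSS +/- `promoter_pad`); anchor order does not matter. Associations
#' shorter than `min_length` are excluded because anchors at the assay
#' resolution cannot separate the two ends. Only cis loops are considered;
#' pass the union of loops across sources to pool cell lines.
#'
#' @param scored Scored edge tibble ([association_score()] output).
#' @param loops Loop tibble from [read_loops()].
#' @param genes Gene tibble (supplies TSS and chromosome).
#' @param clusters Cluster tibble (supplies spans).
#' @param min_length Minimum association length in bp (default 10000).
#' @param promoter_pad Promoter half-width around the TSS in bp (default 2500).
#' @return Tibble with `gene_id`, `cluster_id`, `d`, `score`,
#'   `overlaps_loop`.
#' @export
overlap_associations <- function(scored, loops, genes, clusters,
                                 min_length = 10000, promoter_pad = 2500) {
  calls <- filter(scored, abs(.data$d) >= min_length)
  cis <- filter(loops, .data$is_cis)
  proms <- genes |>
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              start = pmax(.data$tss - promoter_pad, 0),
              end = .data$tss + promoter_pad + 1)
  spans <- select(clusters, "cluster_id", "chrom", "start", "end")
  a1 <- select(cis, chrom = "chrom1", start = "start1", end = "end1")
  a2 <- select(cis, chrom = "chrom2", start = "start2", end = "end2")
  hit_pairs <- function(feat, anchors, id_col) {
    overlap_pairs(feat, anchors) |>
      transmute(id = feat[[id_col]][.data$query], loop = .data$subject)
  }
  c_a1 <- hit_pairs(spans, a1, "cluster_id")
  c_a2 <- hit_pairs(spans, a2, "cluster_id")
  g_a1 <- hit_pairs(proms, a1, "gene_id")
  g_a2 <- hit_pairs(proms, a2, "gene_id")
  ov <- bind_rows(
    inner_join(c_a1, g_a2, by = "loop", suffix = c("_c", "_g"),
               relationship = "many-to-many"),
    inner_join(c_a2, g_a1, by = "loop", suffix = c("_c", "_g"),
               relationship = "many-to-many")
  ) |>
    distinct(cluster_id = .data$id_c, gene_id = .data$id_g) |>
    mutate(overlaps_loop = TRUE)
  calls |>
    select("gene_id", "cluster_id", "d", "score") |>
    left_join(ov, by = c("gene_id", "cluster_id")) |>
    mutate(overlaps_loop = replace_na(.data$overlaps_loop, FALSE))
}

#' Loop-overlap ratio by association-score bin
#'
#' Groups overlap calls into equal-count score bins (deciles by default) and
#' reports the fraction of associations overlapping a loop per bin, with a
#' binomial standard error.
#'
#' @param calls Tibble from [overlap_associations()].
#' @param n_bins Number of quantile bins (default 10); reduced with a
#'   warning when there are fewer distinct scores.
#' @return Tibble with `bin`, `n`, `n_overlap`, `ratio`, `se`, `mean_score`.
#' @export
score_bin_enrichment <- function(calls, n_bins = 10) {
  if (n_distinct(calls$score) < n_bins) {
    n_bins <- max(1, n_distinct(calls$score))
    warn(sprintf("fewer distinct scores than bins; using %d bins", n_bins))
  }
  calls |>
    arrange(.data$score, .data$gene_id, .data$cluster_id) |>
    mutate(bin = ntile(row_number(), n_bins)) |>
    group_by(.data$bin) |>
    summarise(n = n(), n_overlap = sum(.data$overlaps_loop),
              ratio = mean(.data$overlaps_loop),
              se = sqrt(.data$ratio * (1 - .data$ratio) / .data$n),
              mean_score = mean(.data$score), .groups = "drop")
}

# ROC curve with grouped ties and trapezoidal AUC (equals the midrank
# Mann-Whitney U statistic divided by n_pos * n_neg)
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  tibble(threshold = c(Inf, s[last]),
         tpr = c(0, tp[last] / sum(y)),
         fpr = c(0, fp[last] / sum(!y)))
}

auc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

#' Predictive power of binned potential for multi-loop hubs
#'
#' Tiles the genome at the loop-anchor resolution, sums cluster potentials
#' and counts anchored loops per bin, then for each loop-count threshold
#' treats bins with at least that many loops as positives and computes the
#' ROC of bin potential with midrank tie handling. Restricting to
#' promoter-containing bins mirrors the promoter-capture design.
#'
#' @param potentials Tibble from [regulatory_potential()].
#' @param loops Loop tibble.
#' @param clusters Cluster tibble.
#' @param thresholds Integer vector of loop-count thresholds.
#' @param bin_size Bin width in bp (default 5000).
#' @param promoter_only Restrict to bins containing a gene promoter.
#' @param genes Gene tibble, required when `promoter_only = TRUE`.
#' @param promoter_pad Promoter half-width in bp (default 2500).
#' @return Tibble with `threshold`, `n_pos`, `n_neg`, `auc` and a `curve`
#'   list-column of (fpr, tpr) points; thresholds with no positives or no
#'   negatives get `auc = NA`.
#' @export
hub_auc <- function(potentials, loops, clusters, thresholds = 1:3,
                    bin_size = 5000, promoter_only = FALSE, genes = NULL,
                    promoter_pad = 2500) {
  bins <- bin_potentials(potentials, clusters, bin_size) |>
    left_join(count_anchored_loops(loops, bin_size),
              by = c("chrom", "bin_start")) |>
    mutate(loop_count = replace_na(.data$loop_count, 0L))
  if (promoter_only) {
    if (is.null(genes)) abort("promoter_only = TRUE requires `genes`")
    proms <- genes |>
      transmute(chrom = .data$chrom,
                start = pmax(.data$tss - promoter_pad, 0),
                end = .data$tss + promoter_pad + 1)
    bt <- mutate(bins, start = .data$bin_start, end = .data$bin_start + bin_size)
    hits <- overlap_pairs(bt, proms)
    bins <- bins[sort(unique(hits$query)), , drop = FALSE]
  }
  map(thresholds, function(thr) {
    pos <- bins$loop_count >= thr
    if (sum(pos) == 0 || sum(!pos) == 0) {
      return(tibble(threshold = thr, n_pos = sum(pos), n_neg = sum(!pos),
                    auc = NA_real_, curve = list(NULL)))
    }
    curve <- roc_points(bins$potential, pos)
    tibble(threshold = thr, n_pos = sum(pos), n_neg = sum(!pos),
           auc = auc_trapezoid(curve), curve = list(curve))
  }) |> list_rbind()
}
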