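#' Collapse nearby CpG probes into clusters by complete linkage
#'
#' Agglomerative complete-linkage clustering of probe positions per
#' chromosome, merging nearest pairs first (ties broken toward the leftmost
#' coordinate) while the merged cluster's maximum pairwise distance stays
#' within `diameter` (inclusive). In one dimension complete-linkage clusters
#' are contiguous, so only adjacent clusters are candidate merges; probes
#' separated by more than `diameter` can never share a cluster, which allows
#' gap pre-splitting for speed.
#'
#' A cluster is flagged `in_island` when any member probe is in a CpG island.
#'
#' @param probes Tibble with `probe_id`, `chrom`, `pos`, `in_island`.
#' @param diameter Maximum within-cluster pairwise distance in bp (default 200).
#' @return Tibble with `cluster_id`, `chrom`, `start`, `end` (half-open span
#'   covering member probes), `representative_pos` (midpoint of the span),
#'   `n_probes`, `in_island`, and a `members` list-column of probe ids.
#' @export
cluster_probes <- function(probes, diameter = 200) {
  if (diameter < 0) abort("diameter must be non-negative")
  if (nrow(probes) == 0) abort("no probes to cluster")
  probes <- arrange(probes, .data$chrom, .data$pos)
  out <- probes |>
    group_by(.data$chrom) |>
    group_map(function(df, key) {
      assign <- complete_linkage_1d(df$pos, diameter)
      df |>
        mutate(.grp = assign) |>
        group_by(.data$.grp) |>
        summarise(start = min(.data$pos),
                  end = max(.data$pos) + 1,
                  n_probes = n(),
                  in_island = any(.data$in_island),
                  members = list(.data$probe_id),
                  .groups = "drop") |>
        mutate(chrom = key$chrom) |>
        select(-".grp")
    }) |>
    list_rbind() |>
    arrange(.data$chrom, .data$start) |>
    mutate(representative_pos = floor((.data$start + .data$end - 1) / 2),
           cluster_id = sprintf("%s:%d-%d", .data$chrom,
                                as.integer(.data$start), as.integer(.data$end))) |>
    select("cluster_id", "chrom", "start", "end", "representative_pos",
           "n_probes", "in_island", "members")
  out
}

# complete linkage on sorted 1-D positions, cut at `diameter`; returns a
# cluster index per input position (positions must be sorted ascending)
complete_linkage_1d <- function(pos, diameter) {
  n <- length(pos)
  if (n == 1) return(1L)
  # pre-split at gaps > diameter: probes across such gaps can never merge
  gap <- which(diff(pos) > diameter)
  chunk <- cumsum(c(1L, seq_len(n - 1) %in% gap))
  offset <- 0L
  assign <- integer(n)
  for (ch in unique(chunk)) {
    idx <- which(chunk == ch)
    p <- pos[idx]
    # contiguous clusters as (lo, hi) index ranges into p
    lo <- seq_along(p)
    hi <- seq_along(p)
    repeat {
      if (length(lo) == 1) break
      # complete-linkage distance of adjacent pair i, i+1 = span of the merge
      d <- p[hi[-1]] - p[lo[-length(lo)]]
      i <- which.min(d)  # ties -> leftmost
      if (d[i] > diameter) break
      hi[i] <- hi[i + 1]
      lo <- lo[-(i + 1)]
      hi <- hi[-(i + 1)]
    }
    cl <- rep.int(seq_along(lo), hi - lo + 1L)
    assign[idx] <- cl + offset
    offset <- offset + length(lo)
  }
  assign
}

#' Average probe beta values within clusters
#'
#' The cluster row is the arithmetic mean of its member probe rows per
#' sample, ignoring missing members; a sample with all members missing gets
#' a missing cell.
#'
#' @param betas Probe-by-sample numeric matrix (rownames = probe ids).
#' @param clusters Cluster tibble from [cluster_probes()].
#' @return Cluster-by-sample matrix (rownames = cluster ids).
#' @export
average_cluster_beta <- function(betas, clusters) {
  members <- unlist(clusters$members)
  missing <- setdiff(members, rownames(betas))
  if (length(missing) > 0) {
    abort(paste0("cluster member absent from beta matrix: ", missing[1]))
  }
  grp <- rep(clusters$cluster_id, lengths(clusters$members))
  sub <- betas[members, , drop = FALSE]
  obs <- !is.na(sub)
  sums <- rowsum(ifelse(obs, sub, 0), grp, reorder = FALSE)
  counts <- rowsum(obs + 0, grp, reorder = FALSE)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out[clusters$cluster_id, , drop = FALSE]
}

#' Build the candidate gene-cluster network
#'
#' Connects every gene to every probe cluster whose representative position
#' lies within `radius` bp of the gene's TSS on the same chromosome. The
#' signed distance `d` is oriented by strand so that negative means upstream
#' of the TSS in the gene's reading direction. `k` records the
#' neighbourhood size per gene, including genes with zero neighbours.
#'
#' @param genes Gene tibble from [read_gene_annotation()].
#' @param clusters Cluster tibble from [cluster_probes()].
#' @param radius Candidate window half-width in bp (default 1e6).
#' @return Object of class `methnet_network`: list with `edges` (tibble
#'   `gene_id`, `cluster_id`, `d`, `in_gene_body`), `k` (tibble `gene_id`,
#'   `k`) and `radius`.
#' @export
build_candidate_network <- function(genes, clusters, radius = 1e6) {
  edges <- inner_join(
    select(genes, "gene_id", "chrom", "tss", "strand",
           gene_start = "start", gene_end = "end"),
    select(clusters, "cluster_id", "chrom", "representative_pos",
           cl_start = "start", cl_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(abs(.data$representative_pos - .data$tss) <= radius) |>
    mutate(d = ifelse(.data$strand == "-",
                      .data$tss - .data$representative_pos,
                      .data$representative_pos - .data$tss),
           in_gene_body = .data$cl_start < .data$gene_end &
             .data$cl_end > .data$gene_start) |>
    select("gene_id", "cluster_id", "d", "in_gene_body") |>
    arrange(.data$gene_id, .data$cluster_id)
  k <- edges |>
    count(.data$gene_id, name = "k") |>
    right_join(tibble(gene_id = genes$gene_id), by = "gene_id") |>
    mutate(k = replace_na(.data$k, 0L)) |>
    arrange(.data$gene_id)
  structure(list(edges = edges, k = k, radius = radius),
            class = "methnet_network")
}

#' @export
print.methnet_network <- function(x, ...) {
  cat(sprintf("<methnet_network> %d candidate edges, %d genes (radius %g bp)\n",
              nrow(x$edges), nrow(x$k), x$radius))
  invisible(x)
}
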