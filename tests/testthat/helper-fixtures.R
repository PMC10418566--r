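# shared fixtures, computed lazily once per test run
.cache <- new.env(parent = emptyenv())

get_smoke <- function() {
  if (is.null(.cache$fx)) .cache$fx <- smoke_fixture(seed = 7)
  .cache$fx
}

# the full pipeline fit on the smoke fixture (slowest shared object)
get_smoke_fit <- function() {
  if (is.null(.cache$res)) {
    fx <- get_smoke()
    .cache$res <- suppressWarnings(
      methnet_pipeline(fx$genes, fx$probes, fx$methylation, fx$expression,
                       fx$samples, seed = 7)
    )
  }
  .cache$res
}

# independent complete-linkage oracle: stats::hclust + cutree at the diameter
oracle_cluster_1d <- function(pos, diameter) {
  if (length(pos) == 1) return(1L)
  hc <- stats::hclust(stats::dist(pos), method = "complete")
  stats::cutree(hc, h = diameter)
}

# partitions compared up to label renaming
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# brute-force candidate edges: all gene x cluster pairs filtered by distance
oracle_candidate_edges <- function(genes, clusters, radius) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(clusters))) {
      if (genes$chrom[i] != clusters$chrom[j]) next
      if (abs(clusters$representative_pos[j] - genes$tss[i]) <= radius) {
        out[[length(out) + 1]] <- data.frame(gene_id = genes$gene_id[i],
                                             cluster_id = clusters$cluster_id[j])
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$gene_id, df$cluster_id), ]
}

# 0-based half-open interval intersection test
iv_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# brute-force loop overlap oracle: all (association, loop) pairs
oracle_overlap <- function(calls, loops, genes, clusters, promoter_pad = 2500) {
  g <- genes[match(calls$gene_id, genes$gene_id), ]
  cl <- clusters[match(calls$cluster_id, clusters$cluster_id), ]
  vapply(seq_len(nrow(calls)), function(i) {
    ps <- max(g$tss[i] - promoter_pad, 0); pe <- g$tss[i] + promoter_pad + 1
    cs <- cl$start[i]; ce <- cl$end[i]
    any(vapply(seq_len(nrow(loops)), function(l) {
      if (!loops$is_cis[l] || loops$chrom1[l] != g$chrom[i]) return(FALSE)
      (iv_overlap(loops$start1[l], loops$end1[l], cs, ce) &&
         iv_overlap(loops$start2[l], loops$end2[l], ps, pe)) ||
        (iv_overlap(loops$start2[l], loops$end2[l], cs, ce) &&
           iv_overlap(loops$start1[l], loops$end1[l], ps, pe))
    }, logical(1)))
  }, logical(1))
}

# Mann-Whitney U identity for the AUC (midrank ties)
oracle_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# minimal hand-built context network for consensus unit tests
make_ctx <- function(context, edges, models) {
  structure(list(context = context, edges = edges, models = models),
            class = "methnet_context_network")
}

# minimal candidate network wrapper
make_net <- function(edges, k) {
  structure(list(edges = edges, k = k, radius = 1e6),
            class = "methnet_network")
}
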