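#' Distance-rank profile of regulatory effect
#'
#' Candidate edges outside the gene body are split into CpG-island and
#' non-island classes and ranked per gene within each class by absolute
#' distance: -1 is the closest upstream cluster, -2 the second closest, and
#' +1, +2, ... downstream. Per (rank, class) the mean absolute distance, the
#' mean consensus coefficient (candidate edges without a retained
#' association count as zero) and the association probability
#' (retained / candidate) are reported. Gene-body edges are summarized
#' separately under `region = "gene_body"`.
#'
#' @param network `methnet_network` of candidate edges.
#' @param consensus Consensus edge tibble from [build_consensus()].
#' @param clusters Cluster tibble (supplies `in_island`).
#' @return Tibble with `region`, `rank`, `island`, `n_candidate`,
#'   `n_retained`, `mean_abs_distance`, `mean_coefficient`,
#'   `association_probability`.
#' @export
distance_rank_profile <- function(network, consensus, clusters) {
  edges <- network$edges |>
    left_join(select(clusters, "cluster_id", "in_island"), by = "cluster_id") |>
    left_join(select(consensus, "gene_id", "cluster_id", "coefficient"),
              by = c("gene_id", "cluster_id")) |>
    mutate(retained = !is.na(.data$coefficient),
           coefficient = replace_na(.data$coefficient, 0),
           island = ifelse(.data$in_island, "island", "non_island"))
  outside <- edges |>
    filter(!.data$in_gene_body) |>
    mutate(side = ifelse(.data$d < 0, "upstream", "downstream")) |>
    group_by(.data$gene_id, .data$island, .data$side) |>
    mutate(rank = rank(abs(.data$d), ties.method = "first") *
             ifelse(.data$side == "upstream", -1L, 1L)) |>
    ungroup()
  prof_out <- outside |>
    group_by(region = .data$side, rank = .data$rank, island = .data$island) |>
    summarise(n_candidate = n(),
              n_retained = sum(.data$retained),
              mean_abs_distance = mean(abs(.data$d)),
              mean_coefficient = mean(.data$coefficient),
              association_probability = mean(.data$retained),
              .groups = "drop")
  prof_body <- edges |>
    filter(.data$in_gene_body) |>
    group_by(.data$island) |>
    summarise(n_candidate = n(),
              n_retained = sum(.data$retained),
              mean_abs_distance = mean(abs(.data$d)),
              mean_coefficient = mean(.data$coefficient),
              association_probability = mean(.data$retained),
              .groups = "drop") |>
    mutate(region = "gene_body", rank = NA_integer_, .before = 1)
  bind_rows(prof_out, prof_body) |>
    arrange(.data$region, .data$rank, .data$island)
}

# overlapping (query index, subject index, width) pairs between two
# interval tibbles with chrom/start/end columns, via IRanges per chromosome
overlap_pairs <- function(query, subject) {
  out <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) == 0) next
    ov <- IRanges::pintersect(qr[S4Vectors::queryHits(hits)],
                              sr[S4Vectors::subjectHits(hits)])
    out[[ch]] <- tibble(query = qi[S4Vectors::queryHits(hits)],
                        subject = si[S4Vectors::subjectHits(hits)],
                        width = IRanges::width(ov))
  }
  if (length(out) == 0) {
    return(tibble(query = integer(), subject = integer(), width = integer()))
  }
  list_rbind(unname(out))
}

#' Label clusters by their most-overlapped chromatin state
#'
#' Each cluster gets the state with the largest total overlap (in bp,
#' summed across cell types when the annotation stacks several tracks).
#' Ties are broken by `state_priority` (earlier wins); clusters overlapping
#' no state get `unassigned_label`.
#'
#' @param clusters Cluster tibble.
#' @param states Interval annotation tibble (`chrom`, `start`, `end`,
#'   `label`) from [read_interval_annotation()].
#' @param state_priority Character vector fixing tie-break order; defaults
#'   to alphabetical.
#' @param unassigned_label Label for clusters with no overlap.
#' @return Tibble with `cluster_id`, `state`.
#' @export
label_clusters_by_state <- function(clusters, states,
                                    state_priority = NULL,
                                    unassigned_label = "Low Signal") {
  prio <- state_priority %||% sort(unique(states$label))
  pairs <- overlap_pairs(clusters, states)
  lab <- pairs |>
    mutate(cluster_id = clusters$cluster_id[.data$query],
           label = states$label[.data$subject]) |>
    group_by(.data$cluster_id, .data$label) |>
    summarise(bp = sum(.data$width), .groups = "drop") |>
    group_by(.data$cluster_id) |>
    arrange(desc(.data$bp), match(.data$label, prio), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("cluster_id", state = "label")
  tibble(cluster_id = clusters$cluster_id) |>
    left_join(lab, by = "cluster_id") |>
    mutate(state = replace_na(.data$state, unassigned_label))
}

# common least-squares enrichment fit: potential ~ terms, BH-adjusted
enrichment_lm <- function(df, formula, drop_intercept = TRUE) {
  fit <- lm(formula, data = df)
  sm <- summary(fit)$coefficients
  out <- tibble(term = rownames(sm), effect = sm[, 1], stderr = sm[, 2],
                p = sm[, 4])
  if (drop_intercept) out <- filter(out, .data$term != "(Intercept)")
  mutate(out, p_adj = p.adjust(.data$p, method = "BH"))
}

#' Chromatin-state enrichment of regulatory potential
#'
#' Fits `potential ~ state` by least squares with `reference_label` as the
#' baseline; coefficients are per-state shifts in mean potential relative to
#' the reference, with Benjamini-Hochberg adjusted p-values across states.
#'
#' @param potentials Tibble from [regulatory_potential()].
#' @param cluster_states Tibble `cluster_id`, `state` from
#'   [label_clusters_by_state()].
#' @param reference_label Baseline state (default "Low Signal").
#' @return Tibble with `term`, `effect`, `stderr`, `p`, `p_adj`, `n`.
#' @export
state_enrichment <- function(potentials, cluster_states,
                             reference_label = "Low Signal") {
  df <- inner_join(potentials, cluster_states, by = "cluster_id")
  if (!reference_label %in% df$state) {
    abort(paste0("reference state absent: ", reference_label))
  }
  df$state <- stats::relevel(factor(df$state), ref = reference_label)
  if (nlevels(df$state) == 1) {
    return(tibble(term = character(), effect = numeric(), stderr = numeric(),
                  p = numeric(), p_adj = numeric(), n = integer()))
  }
  counts <- count(df, .data$state)
  enrichment_lm(df, potential ~ state) |>
    mutate(term = sub("^state", "", .data$term)) |>
    left_join(counts, by = c(term = "state")) |>
    rename(n = "n")
}

#' Transcription-factor binding enrichment of regulatory potential
#'
#' One joint multiple regression of potential on all factor-binding
#' indicators simultaneously, so co-binding factors compete for the signal;
#' the intercept represents unbound chromatin. Factors bound nowhere are
#' dropped with a warning; perfectly collinear factors are unidentifiable
#' and all but the lexicographically first are dropped with a warning.
#'
#' @param potentials Tibble from [regulatory_potential()].
#' @param binding Binary cluster-by-factor matrix (rownames = cluster ids)
#'   or tibble with a `cluster_id` column and one 0/1 column per factor.
#' @return Tibble with `term` (factor), `effect`, `stderr`, `p`, `p_adj`,
#'   plus attribute `dropped` naming unidentifiable factors.
#' @export
tfbs_enrichment <- function(potentials, binding) {
  if (!is.matrix(binding)) {
    binding <- as.data.frame(binding)
    rownames(binding) <- binding$cluster_id
    binding$cluster_id <- NULL
    binding <- as.matrix(binding)
  }
  stopifnot(all(binding %in% c(0, 1)))
  binding <- binding[, order(colnames(binding)), drop = FALSE]
  unbound <- colSums(binding) == 0
  if (any(unbound)) {
    warn(paste0("factor(s) bound nowhere, dropped: ",
                paste(colnames(binding)[unbound], collapse = ", ")))
    binding <- binding[, !unbound, drop = FALSE]
  }
  common <- intersect(potentials$cluster_id, rownames(binding))
  df <- data.frame(potential = potentials$potential[match(common, potentials$cluster_id)],
                   binding[common, , drop = FALSE], check.names = FALSE)
  fit <- lm(potential ~ ., data = df)
  aliased <- names(which(is.na(coef(fit))))
  aliased <- gsub("`", "", aliased)
  if (length(aliased) > 0) {
    warn(paste0("collinear factor(s) unidentifiable, dropped: ",
                paste(aliased, collapse = ", ")))
    df <- df[, !(names(df) %in% aliased), drop = FALSE]
    fit <- lm(potential ~ ., data = df)
  }
  sm <- summary(fit)$coefficients
  out <- tibble(term = gsub("`", "", rownames(sm)),
                effect = sm[, 1], stderr = sm[, 2], p = sm[, 4]) |>
    filter(.data$term != "(Intercept)") |>
    mutate(p_adj = p.adjust(.data$p, method = "BH"))
  attr(out, "dropped") <- aliased
  out
}

#' Sum cluster potentials into genomic bins
#'
#' @param potentials Tibble from [regulatory_potential()].
#' @param clusters Cluster tibble (clusters are assigned to the bin of
#'   their representative position).
#' @param bin_size Bin width in bp.
#' @return Tibble with `chrom`, `bin_start`, `potential`, `n_clusters`.
#' @export
bin_potentials <- function(potentials, clusters, bin_size) {
  inner_join(potentials,
             select(clusters, "cluster_id", "chrom", "representative_pos"),
             by = "cluster_id") |>
    mutate(bin_start = floor(.data$representative_pos / bin_size) * bin_size) |>
    group_by(.data$chrom, .data$bin_start) |>
    summarise(potential = sum(.data$potential), n_clusters = n(),
              .groups = "drop")
}

#' Count loop anchors per genomic bin
#'
#' Each cis loop contributes one count to every bin overlapped by each of
#' its anchors.
#'
#' @param loops Loop tibble from [read_loops()] (trans rows are ignored).
#' @param bin_size Bin width in bp.
#' @return Tibble with `chrom`, `bin_start`, `loop_count`.
#' @export
count_anchored_loops <- function(loops, bin_size) {
  cis <- filter(loops, .data$is_cis)
  anchors <- bind_rows(
    select(cis, chrom = "chrom1", start = "start1", end = "end1"),
    select(cis, chrom = "chrom2", start = "start2", end = "end2")
  )
  if (nrow(anchors) == 0) {
    return(tibble(chrom = character(), bin_start = numeric(), loop_count = integer()))
  }
  anchors |>
    mutate(first_bin = floor(.data$start / bin_size),
           last_bin = floor((.data$end - 1) / bin_size)) |>
    rowwise() |>
    reframe(chrom = .data$chrom,
            bin_start = seq(.data$first_bin, .data$last_bin) * bin_size) |>
    count(.data$chrom, .data$bin_start, name = "loop_count")
}

#' Loop-count quartile enrichment of binned potential
#'
#' Bins the genome at `bin_size`, sums cluster potentials per bin, counts
#' anchored loops per bin, splits loop-bearing bins into quartiles of loop
#' count (plus a zero-loop reference stratum) and regresses bin potential on
#' the strata.
#'
#' @param potentials Tibble from [regulatory_potential()].
#' @param loops Loop tibble.
#' @param clusters Cluster tibble.
#' @param bin_size Bin width in bp (default 2500).
#' @return Tibble with `term` (quartile), `effect`, `stderr`, `p`, `p_adj`,
#'   `n`; attribute `bins` holds the per-bin table.
#' @export
loop_quartile_enrichment <- function(potentials, loops, clusters, bin_size = 2500) {
  bins <- bin_potentials(potentials, clusters, bin_size) |>
    left_join(count_anchored_loops(loops, bin_size),
              by = c("chrom", "bin_start")) |>
    mutate(loop_count = replace_na(.data$loop_count, 0L))
  looped <- filter(bins, .data$loop_count > 0)
  if (nrow(looped) == 0) {
    warn("no loops overlap any potential-bearing bin; zero contrasts")
    out <- tibble(term = character(), effect = numeric(), stderr = numeric(),
                  p = numeric(), p_adj = numeric(), n = integer())
    attr(out, "bins") <- bins
    return(out)
  }
  qs <- unique(quantile(looped$loop_count, probs = seq(0, 1, 0.25), type = 1))
  if (length(qs) < 5) {
    warn("fewer than 4 distinct loop-count quartiles; collapsing strata")
  }
  bins <- bins |>
    mutate(stratum = ifelse(.data$loop_count == 0, "none",
                            paste0("Q", as.integer(cut(.data$loop_count,
                                                       breaks = c(-Inf, qs[-1]),
                                                       labels = FALSE)))))
  bins$stratum <- stats::relevel(factor(bins$stratum), ref = "none")
  counts <- count(bins, .data$stratum)
  out <- enrichment_lm(bins, potential ~ stratum) |>
    mutate(term = sub("^stratum", "", .data$term)) |>
    left_join(counts, by = c(term = "stratum")) |>
    rename(n = "n")
  attr(out, "bins") <- bins
  out
}

#' Survival association of element methylation
#'
#' For each selected element, fits a stratified varying-slope proportional
#' hazards model of overall survival on the element's beta value,
#' `Surv(os_time, os_event) ~ beta * strata(context)`: the main `beta`
#' coefficient is the pooled log-hazard per unit beta and the interaction
#' terms are per-context deviations. Elements in the bottom
#' `variance_quantile` of methylation variance are excluded; from the rest,
#' all hubs plus `n_random` randomly selected elements are tested (seeded).
#' Contexts with fewer than two events are dropped per element; an element
#' whose model cannot be fitted (e.g. all samples censored) is reported with
#' missing estimates rather than aborting the scan.
#'
#' @param cluster_betas Cluster-by-sample beta matrix.
#' @param samples Sample tibble with `os_event`, `os_time`, `context`.
#' @param hubs Character vector of hub cluster ids (or a [call_hubs()]
#'   result, from which hubs are taken).
#' @param n_random Number of non-hub elements to sample (default: all
#'   remaining after the variance filter).
#' @param variance_quantile Fraction of lowest-variance elements to exclude
#'   (default 0.25).
#' @param seed Seed for the random complement.
#' @return Tibble with `cluster_id`, `term` (`"pooled"` or a context name),
#'   `effect`, `stderr`, `z`, `p`, `p_adj` (BH within the pooled family and
#'   within the per-context family separately).
#' @export
survival_association <- function(cluster_betas, samples, hubs = NULL,
                                 n_random = NULL, variance_quantile = 0.25,
                                 seed = 1) {
  if (is.data.frame(hubs)) hubs <- hubs$cluster_id[hubs$is_hub]
  hubs <- hubs %||% character()
  mu <- rowMeans(cluster_betas, na.rm = TRUE)
  v <- rowMeans((cluster_betas - mu)^2, na.rm = TRUE)
  keep <- rownames(cluster_betas)[v >= quantile(v, variance_quantile)]
  pool <- setdiff(keep, hubs)
  set.seed(seed)
  n_random <- min(n_random %||% length(pool), length(pool))
  chosen <- c(intersect(hubs, keep), sort(sample(pool, n_random)))

  surv_ok <- samples |>
    filter(!is.na(.data$os_event), !is.na(.data$os_time),
           .data$sample_id %in% colnames(cluster_betas))
  events_by_ctx <- surv_ok |>
    group_by(.data$context) |>
    summarise(n_events = sum(.data$os_event), .groups = "drop")
  good_ctx <- events_by_ctx$context[events_by_ctx$n_events >= 2]
  surv_ok <- filter(surv_ok, .data$context %in% good_ctx)

  res <- map(chosen, function(cl) {
    df <- surv_ok |>
      mutate(beta = cluster_betas[cl, .data$sample_id]) |>
      filter(!is.na(.data$beta))
    fit <- tryCatch(
      survival::coxph(survival::Surv(os_time, os_event) ~ beta * survival::strata(context),
                      data = df),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      return(tibble(cluster_id = cl, term = "pooled", effect = NA_real_,
                    stderr = NA_real_, z = NA_real_, p = NA_real_))
    }
    sm <- summary(fit)$coefficients
    terms <- rownames(sm)
    tibble(cluster_id = cl,
           term = ifelse(terms == "beta", "pooled",
                         sub("^beta:survival::strata\\(context\\)context=", "",
                             terms)),
           effect = sm[, "coef"], stderr = sm[, "se(coef)"],
           z = sm[, "z"], p = sm[, "Pr(>|z|)"])
  }) |> list_rbind()
  res |>
    group_by(pooled = .data$term == "pooled") |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    select(-"pooled")
}
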