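#' Generate a toy genome annotation and probe manifest
#'
#' One chromosome carrying `n_genes` protein-coding genes with random
#' strands, and `n_probes` CpG probes laid out in short bursts so that the
#' 200 bp complete-linkage clustering is exercised. Genes are grouped into
#' `n_gene_clumps` gene-dense loci (mirroring the clumped organisation of
#' real genomes), which also guarantees that a promoter-proximal regulator
#' can reach several genes inside its 1 Mb window. One probe burst is
#' centred on every gene's TSS (array probes concentrate at promoter
#' islands); the remaining bursts are placed uniformly. Island membership is
#' assigned per burst. Output is a pure function of the parameters and seed.
#'
#' @param n_genes,n_probes Counts (both must be positive).
#' @param chrom_length Chromosome length in bp.
#' @param island_fraction Fraction of bursts flagged as CpG islands.
#' @param n_bursts Number of probe bursts in addition to the per-gene
#'   promoter bursts.
#' @param n_gene_clumps Number of gene-dense loci.
#' @param clump_halfwidth Half-width of each locus in bp.
#' @param seed Seed.
#' @return List with `genes` and `probes` tibbles, `chrom` and
#'   `chrom_length`.
#' @export
make_toy_genome <- function(n_genes = 20, n_probes = 400, chrom_length = 1e7,
                            island_fraction = 0.5, n_bursts = 60,
                            n_gene_clumps = 3, clump_halfwidth = 4e5,
                            seed = 1) {
  if (n_genes <= 0) abort("n_genes must be positive")
  if (n_probes <= 0) abort("n_probes must be positive")
  if (chrom_length < 2000 * n_genes + 600 * (n_bursts + n_genes)) {
    abort("feature density exceeds chrom_length")
  }
  set.seed(seed)
  chrom <- "chrT"
  margin <- round(chrom_length * 0.02)
  centers_g <- margin + clump_halfwidth +
    (seq_len(n_gene_clumps) - 0.5) / n_gene_clumps *
    (chrom_length - 2 * (margin + clump_halfwidth))
  clump <- rep_len(seq_len(n_gene_clumps), n_genes)
  repeat {
    tss <- sort(round(centers_g[clump] +
                        runif(n_genes, -clump_halfwidth, clump_halfwidth)))
    # promoters of distinct genes should not share a 5 kb loop-anchor bin
    if (n_genes == 1 || min(diff(tss)) >= 6000) break
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  body_len <- sample(5000:50000, n_genes, replace = TRUE)
  genes <- tibble(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    symbol = sprintf("Gene%03d", seq_len(n_genes)),
    chrom = chrom,
    start = ifelse(strand == "+", tss, tss + 1 - body_len),
    end = ifelse(strand == "+", tss + body_len, tss + 1),
    strand = strand,
    tss = tss
  )
  centers <- c(tss, sample(seq(margin, chrom_length - margin), n_bursts))
  nb <- length(centers)
  burst_island <- runif(nb) < island_fraction
  sizes <- as.vector(rmultinom(1, n_probes, rep(1, nb)))
  pos <- unlist(map(seq_len(nb), function(b) {
    if (sizes[b] == 0) return(integer())
    centers[b] + sample(-140:140, sizes[b])
  }))
  island <- rep(burst_island, sizes)
  ord <- order(pos)
  probes <- tibble(
    probe_id = sprintf("cg%06d", seq_along(pos)),
    chrom = chrom,
    pos = pos[ord],
    in_island = island[ord]
  )
  list(genes = genes, probes = probes, chrom = chrom,
       chrom_length = chrom_length)
}

#' Plant a ground-truth regulatory network on a candidate network
#'
#' Every gene receives `n_per_gene` true edges: one to a shared "hub"
#' cluster (a promoter-proximal cluster regulating at least
#' `hub_targets` genes, emulating a multi-gene cis-regulatory hub) and the
#' rest to random candidate neighbours. Hub coefficients are drawn from
#' `hub_beta_range` (negative: methylation silences), other edges from
#' `beta_range` with random signs.
#'
#' @param network `methnet_network` from [build_candidate_network()].
#' @param clusters Cluster tibble.
#' @param genes Gene tibble.
#' @param n_per_gene True edges per gene (default 3).
#' @param n_hubs Number of planted hub clusters (default 3, one per gene clump).
#' @param hub_targets Genes regulated per hub (default 5).
#' @param beta_range,hub_beta_range Coefficient magnitude ranges.
#' @param seed Seed.
#' @return List with `true_edges` tibble (`gene_id`, `cluster_id`, `beta`)
#'   and `true_hubs` (cluster ids).
#' @export
plant_truth <- function(network, clusters, genes, n_per_gene = 3, n_hubs = 3,
                        hub_targets = 5, beta_range = c(1, 2),
                        hub_beta_range = c(1.5, 2.5), seed = 1) {
  set.seed(seed)
  edges <- network$edges
  # promoter-proximal clusters (within 2 kb of a TSS) with enough neighbours
  prom <- edges |>
    filter(abs(.data$d) <= 2000) |>
    distinct(.data$cluster_id)
  degree <- count(edges, .data$cluster_id, name = "deg")
  cand_hubs <- prom |>
    inner_join(degree, by = "cluster_id") |>
    inner_join(select(clusters, "cluster_id", "representative_pos"),
               by = "cluster_id") |>
    filter(.data$deg >= hub_targets + 1) |>
    arrange(desc(.data$deg))
  # spread hubs across loci: a hub monopolizes its 1 Mb neighbourhood, so
  # two hubs closer than that would have to share targets
  hubs <- character()
  hub_pos <- numeric()
  for (i in seq_len(nrow(cand_hubs))) {
    if (length(hubs) == n_hubs) break
    if (all(abs(cand_hubs$representative_pos[i] - hub_pos) > 1e6)) {
      hubs <- c(hubs, cand_hubs$cluster_id[i])
      hub_pos <- c(hub_pos, cand_hubs$representative_pos[i])
    }
  }
  if (length(hubs) < n_hubs) abort("not enough promoter clusters to plant hubs")

  # assign each gene to one reachable hub, balancing hub loads greedily so
  # every hub regulates >= hub_targets genes when reachability allows
  hub_edges <- edges |>
    filter(.data$cluster_id %in% hubs, abs(.data$d) > 2000) |>
    select("gene_id", "cluster_id")
  reach <- split(hub_edges$cluster_id, hub_edges$gene_id)
  load <- setNames(rep(0L, length(hubs)), hubs)
  assign_hub <- map(sample(names(reach)), function(g) {
    h <- reach[[g]][which.min(load[reach[[g]]])]
    load[h] <<- load[h] + 1L
    tibble(gene_id = g, cluster_id = h)
  }) |> list_rbind()
  true_hub_edges <- assign_hub |>
    mutate(beta = -runif(n(), hub_beta_range[1], hub_beta_range[2]))

  other <- map(genes$gene_id, function(g) {
    used <- true_hub_edges$cluster_id[true_hub_edges$gene_id == g]
    need <- n_per_gene - length(used)
    pool <- setdiff(edges$cluster_id[edges$gene_id == g], c(used, hubs))
    if (length(pool) == 0 || need <= 0) return(NULL)
    pick <- sample(pool, min(need, length(pool)))
    tibble(gene_id = g, cluster_id = pick,
           beta = sample(c(-1, 1), length(pick), replace = TRUE) *
             runif(length(pick), beta_range[1], beta_range[2]))
  }) |> list_rbind()
  true_edges <- bind_rows(select(true_hub_edges, "gene_id", "cluster_id", "beta"),
                          other) |>
    arrange(.data$gene_id, .data$cluster_id)
  list(true_edges = true_edges, true_hubs = hubs)
}

# bimodal (low/high methylation) logit-normal beta draws
rbeta_bimodal <- function(n, p_high, spread = 0.5, centers = c(-1.7, 1.7)) {
  comp <- rbinom(n, 1, p_high)
  plogis(rnorm(n, mean = ifelse(comp == 1, centers[2], centers[1]), sd = spread))
}

#' Simulate paired expression and methylation matrices under the model
#'
#' Cluster beta values are drawn per sample from a cluster-specific mixture
#' of low and high methylation states (logit-normal components); member
#' probes copy their cluster's value, so cluster averaging recovers the
#' simulated predictor exactly. Expression follows the linear model the
#' pipeline fits: a sample-type intercept (`tumor_effect` added for tumor
#' samples) plus the planted coefficients times cluster betas plus Gaussian
#' noise. Per-context edge dropout exercises consensus robustness.
#'
#' @param truth List from [plant_truth()].
#' @param genes,clusters Fixture tibbles.
#' @param n_contexts Number of contexts (default 3).
#' @param n_samples_per_context Samples per context (default 150, half
#'   tumor / half normal).
#' @param noise_sd Residual standard deviation (default 0.5).
#' @param tumor_effect Additive tumor shift of baseline expression.
#' @param context_dropout Probability that a planted edge is absent from a
#'   given context (default 0: edges shared across contexts).
#' @param seed Seed.
#' @return List with `expression` (gene x sample), `methylation`
#'   (probe x sample), `cluster_betas` (cluster x sample), `samples`
#'   tibble, and `truth_by_context` (tibble of the edges active per
#'   context).
#' @export
simulate_expression_methylation <- function(truth, genes, clusters,
                                            n_contexts = 3,
                                            n_samples_per_context = 150,
                                            noise_sd = 0.5, tumor_effect = 1,
                                            context_dropout = 0, seed = 1) {
  set.seed(seed)
  contexts <- sprintf("CTX%d", seq_len(n_contexts))
  samples <- map(contexts, function(ctx) {
    n <- n_samples_per_context
    tibble(sample_id = sprintf("%s_S%03d", ctx, seq_len(n)),
           context = ctx,
           sample_type = rep(c("tumor", "normal"), length.out = n),
           os_event = NA_real_, os_time = NA_real_)
  }) |> list_rbind()
  n_all <- nrow(samples)

  p_high <- runif(nrow(clusters), 0.35, 0.65)
  cluster_betas <- t(vapply(seq_len(nrow(clusters)), function(i) {
    rbeta_bimodal(n_all, p_high[i])
  }, numeric(n_all)))
  dimnames(cluster_betas) <- list(clusters$cluster_id, samples$sample_id)

  members <- unlist(clusters$members)
  methylation <- cluster_betas[rep(seq_len(nrow(clusters)),
                                   lengths(clusters$members)), , drop = FALSE]
  rownames(methylation) <- members

  truth_by_context <- crossing(context = contexts, truth$true_edges) |>
    mutate(active = runif(n()) >= context_dropout) |>
    filter(.data$active) |>
    select("context", "gene_id", "cluster_id", "beta")

  base <- rnorm(nrow(genes), 10, 2)
  names(base) <- genes$gene_id
  is_tumor <- samples$sample_type == "tumor"
  expression <- matrix(0, nrow(genes), n_all,
                       dimnames = list(genes$gene_id, samples$sample_id))
  for (g in genes$gene_id) {
    mu <- rep(base[g], n_all) + tumor_effect * is_tumor
    for (ctx in contexts) {
      in_ctx <- samples$context == ctx
      te <- filter(truth_by_context, .data$context == ctx, .data$gene_id == g)
      if (nrow(te) > 0) {
        mu[in_ctx] <- mu[in_ctx] +
          as.vector(t(te$beta) %*% cluster_betas[te$cluster_id, in_ctx, drop = FALSE])
      }
    }
    expression[g, ] <- mu + rnorm(n_all, 0, noise_sd)
  }
  list(expression = expression, methylation = methylation,
       cluster_betas = cluster_betas, samples = samples,
       truth_by_context = truth_by_context)
}

#' Simulate overall survival driven by element methylation
#'
#' Exponential survival times with per-sample log-hazard equal to the sum of
#' planted effects times the sample's cluster betas. Censoring times are
#' exponential with rate proportional to each sample's hazard, which makes
#' censoring non-informative given the covariates and fixes the expected
#' event fraction at `1 - censoring_rate`.
#'
#' @param cluster_betas Cluster-by-sample beta matrix.
#' @param effects Tibble with `cluster_id`, `loghaz` (log-hazard per unit
#'   beta); may be empty for a null simulation.
#' @param samples Sample tibble; `os_event`/`os_time` are overwritten.
#' @param baseline_hazard Baseline hazard per day (default 1e-3).
#' @param censoring_rate Expected fraction censored, in [0, 1).
#' @param seed Seed.
#' @return The sample tibble with simulated `os_event` and `os_time`.
#' @export
simulate_survival <- function(cluster_betas, effects, samples,
                              baseline_hazard = 1e-3, censoring_rate = 0.3,
                              seed = 1) {
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must be in [0, 1)")
  }
  set.seed(seed)
  ids <- samples$sample_id
  lp <- rep(0, length(ids))
  if (nrow(effects) > 0) {
    lp <- as.vector(t(effects$loghaz) %*%
                      cluster_betas[effects$cluster_id, ids, drop = FALSE])
  }
  h <- baseline_hazard * exp(lp)
  t_event <- rexp(length(ids), rate = h)
  if (censoring_rate == 0) {
    samples$os_time <- t_event
    samples$os_event <- 1
    return(samples)
  }
  t_cens <- rexp(length(ids), rate = h * censoring_rate / (1 - censoring_rate))
  samples$os_time <- pmin(t_event, t_cens)
  samples$os_event <- as.numeric(t_event <= t_cens)
  samples
}

#' Simulate chromatin loops and interval annotations from planted structure
#'
#' Loops are placed on loop-eligible associations (length at least
#' `min_length`) with a frequency that increases with the association
#' score: associations are ranked into `n_bins` equal-count score bins and
#' bin `d` receives a deterministic quota of `round((d-1)/(n_bins-1) *
#' n_d)` loops at `enrichment_strength = 1` (interpolated toward a flat 50%
#' quota as the strength drops to 0), assigned to the top-scoring
#' associations of the bin. Quotas make the planted enrichment noise-free;
#' strictly increasing per-bin ratios require at least `9 * n_bins`
#' eligible associations. Each loop joins the 5' anchor bin of the cluster
#' with that of the gene's TSS at `anchor_size` resolution, alternating
#' between two synthetic sources. ChromHMM-style states and TF-binding
#' annotations are derived from the planted hubs: hub cluster spans are
#' labelled "Promoter", other high-score cluster spans "Enhancer", the rest
#' "Low Signal", and a synthetic factor "TF_hub" binds hub clusters.
#'
#' @param scored Scored edge tibble ([association_score()]).
#' @param clusters,genes Fixture tibbles.
#' @param true_hubs Planted hub cluster ids.
#' @param enrichment_strength Coupling of loop placement to score, in
#'   [0, 1].
#' @param anchor_size Loop anchor width in bp (default 5000).
#' @param min_length Minimum association length to be loop-eligible.
#' @param n_bins Number of score bins used for the quotas (default 10).
#' @param seed Seed (used only for the state labels of non-hub clusters).
#' @return List with `loops`, `states`, `binding` (cluster x factor 0/1
#'   matrix) and `eligible` (the loop-eligible association table with an
#'   `has_loop` flag).
#' @export
simulate_loops_and_annotations <- function(scored, clusters, genes, true_hubs,
                                           enrichment_strength = 1,
                                           anchor_size = 5000,
                                           min_length = 10000, n_bins = 10,
                                           seed = 1) {
  set.seed(seed)
  eligible <- scored |>
    filter(abs(.data$d) >= min_length) |>
    arrange(.data$score, .data$gene_id, .data$cluster_id) |>
    mutate(bin = ntile(row_number(), n_bins))
  if (nrow(eligible) < 9 * n_bins) {
    warn("few loop-eligible associations; per-bin ratios may tie")
  }
  eligible <- eligible |>
    group_by(.data$bin) |>
    mutate(quota = {
      frac <- enrichment_strength * (.data$bin[1] - 1) / (n_bins - 1) +
        (1 - enrichment_strength) * 0.5
      round(frac * n())
    },
    has_loop = rank(-.data$score, ties.method = "first") <= .data$quota[1]) |>
    ungroup() |>
    select(-"quota")
  placed <- filter(eligible, .data$has_loop)
  bin_of <- function(pos) floor(pos / anchor_size) * anchor_size
  loops <- placed |>
    left_join(select(clusters, "cluster_id", "chrom",
                     rep_pos = "representative_pos"), by = "cluster_id") |>
    left_join(select(genes, "gene_id", "tss"), by = "gene_id") |>
    transmute(chrom1 = .data$chrom, start1 = bin_of(.data$rep_pos),
              end1 = .data$start1 + anchor_size,
              chrom2 = .data$chrom, start2 = bin_of(.data$tss),
              end2 = .data$start2 + anchor_size,
              source = rep(c("simA", "simB"), length.out = n()),
              is_cis = TRUE)

  med <- stats::median(scored$score)
  strong <- scored |>
    group_by(.data$cluster_id) |>
    summarise(top = max(.data$score), .groups = "drop") |>
    filter(.data$top > med)
  state_of <- ifelse(clusters$cluster_id %in% true_hubs, "Promoter",
                     ifelse(clusters$cluster_id %in% strong$cluster_id,
                            "Enhancer", "Low Signal"))
  states <- tibble(chrom = clusters$chrom,
                   start = pmax(clusters$start - 200, 0),
                   end = clusters$end + 200,
                   label = state_of)
  binding <- cbind(
    TF_hub = as.integer(clusters$cluster_id %in% true_hubs),
    TF_bg = rbinom(nrow(clusters), 1, 0.2)
  )
  rownames(binding) <- clusters$cluster_id
  list(loops = loops, states = states, binding = binding, eligible = eligible)
}

#' Generate well-separated single-association gene/cluster pairs
#'
#' A synthetic panel of `n` genes, each with exactly one candidate cluster
#' at a fixed distance downstream of its TSS and with neighbouring pairs
#' spaced far enough apart that no loop anchor at `anchor_size` resolution
#' can touch more than one pair. Scores are standard normal. The panel
#' isolates score-driven loop-placement statistics from the incidental
#' anchor sharing that occurs in dense genomes, so planted enrichment
#' propagates into overlap calls without crosstalk.
#'
#' @param n Number of associations.
#' @param assoc_distance TSS-to-cluster distance in bp (default 15000,
#'   above the usual 10 kb loop-eligibility floor).
#' @param spacing Distance between consecutive pairs in bp (default 40000).
#' @param anchor_size Anchor resolution the spacing must dominate.
#' @param seed Seed for the scores.
#' @return List with `genes`, `clusters` and `scored` tibbles.
#' @export
simulate_spread_associations <- function(n = 300, assoc_distance = 15000,
                                         spacing = 40000, anchor_size = 5000,
                                         seed = 1) {
  stopifnot(spacing > assoc_distance + 4 * anchor_size)
  set.seed(seed)
  tss <- (seq_len(n) - 1) * spacing + 10000
  genes <- tibble(gene_id = sprintf("sg%04d", seq_len(n)),
                  symbol = sprintf("sg%04d", seq_len(n)),
                  chrom = "chrS", start = tss, end = tss + 1000,
                  strand = "+", tss = tss)
  clusters <- tibble(cluster_id = sprintf("sc%04d", seq_len(n)),
                     chrom = "chrS",
                     start = tss + assoc_distance,
                     end = tss + assoc_distance + 200,
                     representative_pos = tss + assoc_distance + 100,
                     n_probes = 1L, in_island = FALSE)
  scored <- tibble(gene_id = genes$gene_id, cluster_id = clusters$cluster_id,
                   d = assoc_distance + 100, score = rnorm(n))
  list(genes = genes, clusters = clusters, scored = scored)
}

#' Simulate a multi-guide CRISPRi perturb-seq screen
#'
#' Guides are detected in cells independently (Bernoulli per guide, so most
#' cells carry several guides and joint deconvolution is required). Counts
#' are negative-binomial around per-gene baseline abundances, with planted
#' guide effects acting multiplicatively (additively on the log scale) in
#' cells carrying the guide.
#'
#' @param true_guide_effects Tibble with `guide_id`, `gene_id`, `effect`
#'   (log-units).
#' @param guide_meta Tibble with `guide_id`, `region_id`, `is_control`.
#' @param gene_ids Character vector of simulated genes.
#' @param n_cells Number of cells (default 2000).
#' @param guides_per_cell_rate Detection probability per guide per cell.
#' @param depth Mean library size per cell.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param low_expr_genes Gene ids forced to very low abundance (to exercise
#'   the expression floor).
#' @param seed Seed.
#' @return List with `counts` (gene x cell), `X` (cell x guide design),
#'   `assignments` tibble.
#' @export
simulate_perturbseq <- function(true_guide_effects, guide_meta, gene_ids,
                                n_cells = 2000, guides_per_cell_rate = 0.05,
                                depth = 20000, nb_size = 10,
                                low_expr_genes = character(), seed = 1) {
  set.seed(seed)
  guides <- guide_meta$guide_id
  cells <- sprintf("cell%04d", seq_len(n_cells))
  X <- matrix(rbinom(n_cells * length(guides), 1, guides_per_cell_rate),
              n_cells, length(guides), dimnames = list(cells, guides))
  abundance <- stats::rgamma(length(gene_ids), shape = 2, rate = 2)
  abundance[match(low_expr_genes, gene_ids)] <- 1e-3
  abundance <- abundance / sum(abundance)
  logmu <- matrix(log(abundance), length(gene_ids), n_cells,
                  dimnames = list(gene_ids, cells))
  for (i in seq_len(nrow(true_guide_effects))) {
    gid <- true_guide_effects$guide_id[i]
    gg <- true_guide_effects$gene_id[i]
    logmu[gg, X[, gid] == 1] <- logmu[gg, X[, gid] == 1] +
      true_guide_effects$effect[i]
  }
  mu <- exp(logmu)
  mu <- sweep(mu, 2, colSums(mu), "/") * depth
  counts <- matrix(rnbinom(length(mu), mu = mu, size = nb_size),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  assignments <- which(X == 1, arr.ind = TRUE)
  assignments <- tibble(cell_id = cells[assignments[, 1]],
                        guide_id = guides[assignments[, 2]])
  list(counts = counts, X = X, assignments = assignments)
}

#' Assemble the default smoke-scale fixture
#'
#' One call generating every input the pipeline consumes at desk scale:
#' a 20-gene / 400-probe toy genome, a planted truth of 3 true edges per
#' gene including 4 promoter hub clusters with 5 targets each, paired
#' expression/methylation for 3 contexts of 150 samples, survival outcomes
#' driven by the hubs, and the candidate network. Loop, annotation and
#' perturb-seq layers are generated downstream of a fitted network by
#' [simulate_loops_and_annotations()] and [simulate_perturbseq()].
#'
#' @param seed Seed (default 7).
#' @param n_contexts,n_samples_per_context,noise_sd,context_dropout Passed
#'   through to [simulate_expression_methylation()].
#' @return List with `genes`, `probes`, `clusters`, `network`, `truth`,
#'   `expression`, `methylation`, `cluster_betas`, `samples`,
#'   `truth_by_context`.
#' @export
smoke_fixture <- function(seed = 7, n_contexts = 3, n_samples_per_context = 150,
                          noise_sd = 0.5, context_dropout = 0) {
  genome <- make_toy_genome(n_genes = 20, n_probes = 400, seed = seed)
  clusters <- cluster_probes(genome$probes)
  network <- build_candidate_network(genome$genes, clusters)
  truth <- plant_truth(network, clusters, genome$genes, seed = seed + 1)
  sim <- simulate_expression_methylation(
    truth, genome$genes, clusters, n_contexts = n_contexts,
    n_samples_per_context = n_samples_per_context, noise_sd = noise_sd,
    context_dropout = context_dropout, seed = seed + 2)
  surv_effects <- tibble(cluster_id = truth$true_hubs, loghaz = 1)
  samples <- simulate_survival(sim$cluster_betas, surv_effects, sim$samples,
                               seed = seed + 3)
  c(genome[c("genes", "probes")],
    list(clusters = clusters, network = network, truth = truth,
         expression = sim$expression, methylation = sim$methylation,
         cluster_betas = sim$cluster_betas, samples = samples,
         truth_by_context = sim$truth_by_context))
}
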