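#' Log-normalize a cell-by-gene count matrix
#'
#' Counts-per-total scaling followed by `log1p`: each cell's counts are
#' divided by the cell total, multiplied by `scale_factor` and
#' log1p-transformed. Any pre-normalized matrix can be injected downstream
#' instead.
#'
#' @param counts Gene-by-cell integer matrix.
#' @param scale_factor Library-size scale (default 1e4).
#' @return Gene-by-cell matrix of log-normalized values; the scale factor is
#'   kept as an attribute.
#' @export
log_normalize_counts <- function(counts, scale_factor = 1e4) {
  tot <- colSums(counts)
  if (any(tot == 0)) abort("cell with zero total counts")
  out <- log1p(sweep(counts, 2, tot, "/") * scale_factor)
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Filter genes for perturb-seq deconvolution
#'
#' A gene is retained when its TSS lies within `radius` of at least one
#' targeted region and its mean normalized expression (recovered from the
#' log scale) exceeds `min_mean`.
#'
#' @param log_counts Gene-by-cell log-normalized matrix from
#'   [log_normalize_counts()].
#' @param genes Gene tibble (supplies TSS coordinates).
#' @param regions Targeted-region tibble (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param radius Maximum TSS-to-region distance in bp (default 1e6).
#' @param min_mean Mean normalized-expression floor (default 2e-4, on the
#'   per-cell proportion scale).
#' @return Character vector of retained gene ids.
#' @export
filter_perturb_genes <- function(log_counts, genes, regions, radius = 1e6,
                                 min_mean = 2e-4) {
  sf <- attr(log_counts, "scale_factor") %||% 1e4
  mean_norm <- rowMeans(expm1(log_counts)) / sf
  expressed <- rownames(log_counts)[mean_norm > min_mean]
  windows <- genes |>
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              start = pmax(.data$tss - radius, 0),
              end = .data$tss + radius + 1)
  near <- overlap_pairs(windows, regions)
  near_genes <- unique(windows$gene_id[near$query])
  out <- intersect(intersect(expressed, near_genes), rownames(log_counts))
  if (length(out) == 0) abort("no genes pass the perturb-seq filters")
  out
}

#' Build a binary cell-by-guide design matrix
#'
#' @param assignments Tibble with `cell_id`, `guide_id` (one row per
#'   detected guide per cell).
#' @param cells Character vector fixing row order (default: cells present).
#' @param guides Character vector fixing column order (default: guides
#'   present).
#' @return Binary matrix, cells as rows, guides as columns.
#' @export
make_perturb_design <- function(assignments, cells = NULL, guides = NULL) {
  cells <- cells %||% sort(unique(assignments$cell_id))
  guides <- guides %||% sort(unique(assignments$guide_id))
  X <- matrix(0L, length(cells), length(guides), dimnames = list(cells, guides))
  X[cbind(match(assignments$cell_id, cells),
          match(assignments$guide_id, guides))] <- 1L
  X
}

# greedy full-rank column subset keeping the smallest-index columns
drop_collinear <- function(X) {
  base <- cbind(rep(1, nrow(X)))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    cand <- cbind(base, X[, j])
    if (qr(cand)$rank == ncol(cand)) {
      base <- cand
      keep[j] <- TRUE
    }
  }
  keep
}

#' Deconvolve guide effects from a multi-guide perturbation screen
#'
#' Fits, per gene, a joint least-squares model of log-normalized expression
#' on all guide indicators simultaneously (with intercept), with
#' empirical-Bayes moderation of residual variances across genes
#' (limma's `lmFit`/`eBayes`). Because most cells carry several guides, the
#' joint fit separates each guide's contribution from its co-occurring
#' guides. P-values are Benjamini-Hochberg adjusted across all tested
#' (guide, gene) pairs. A targeted region validates when at least one of
#' its guides hits one of its predicted target genes at `p_adj < fdr`;
#' significant effects on non-predicted genes are reported but do not count
#' toward validation.
#'
#' @param log_counts Gene-by-cell log-normalized matrix (rows already
#'   restricted via [filter_perturb_genes()] or not, as desired).
#' @param X Binary cell-by-guide design from [make_perturb_design()].
#' @param guide_meta Tibble with `guide_id`, `region_id`, `is_control`.
#' @param predicted_targets Tibble with `region_id`, `gene_id`: the
#'   network-predicted targets of each targeted region.
#' @param min_cells Guides detected in fewer cells are dropped with a
#'   warning (default 5).
#' @param fdr Adjusted-p threshold for calling interactions (default 0.05).
#' @return Object of class `methnet_perturb`: list with `effects` (tibble
#'   `guide_id`, `gene_id`, `effect`, `t`, `p`, `p_adj`, `predicted_target`),
#'   `regions` (tibble `region_id`, `n_guides`, `n_significant`,
#'   `validated`), `n_validated` and `fdr`.
#' @export
deconvolve_effects <- function(log_counts, X, guide_meta, predicted_targets,
                               min_cells = 5, fdr = 0.05) {
  stopifnot(ncol(log_counts) == nrow(X))
  nz <- colSums(X)
  if (all(nz == 0)) abort("no guide is detected in any cell")
  if (any(nz < min_cells)) {
    warn(paste0("guide(s) in fewer than ", min_cells, " cells dropped: ",
                paste(colnames(X)[nz < min_cells], collapse = ", ")))
    X <- X[, nz >= min_cells, drop = FALSE]
  }
  keep <- drop_collinear(X)
  if (!all(keep)) {
    warn(paste0("collinear guide column(s) dropped: ",
                paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, X)
  fit <- limma::eBayes(limma::lmFit(log_counts, design))
  guides <- colnames(X)
  eff <- fit$coefficients[, guides, drop = FALSE]
  pv <- fit$p.value[, guides, drop = FALSE]
  tv <- fit$t[, guides, drop = FALSE]
  effects <- tibble(
    gene_id = rep(rownames(log_counts), times = length(guides)),
    guide_id = rep(guides, each = nrow(eff)),
    effect = as.vector(eff), t = as.vector(tv), p = as.vector(pv)
  ) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    left_join(select(guide_meta, "guide_id", "region_id", "is_control"),
              by = "guide_id") |>
    left_join(mutate(predicted_targets, predicted_target = TRUE),
              by = c("region_id", "gene_id")) |>
    mutate(predicted_target = replace_na(.data$predicted_target, FALSE)) |>
    select("guide_id", "region_id", "is_control", "gene_id", "effect", "t",
           "p", "p_adj", "predicted_target")
  regions <- effects |>
    filter(!.data$is_control) |>
    group_by(.data$region_id) |>
    summarise(n_guides = n_distinct(.data$guide_id),
              n_significant = sum(.data$p_adj < fdr & .data$predicted_target),
              validated = n_significant >= 1, .groups = "drop")
  structure(list(effects = effects, regions = regions,
                 n_validated = sum(regions$validated), fdr = fdr),
            class = "methnet_perturb")
}

#' @export
print.methnet_perturb <- function(x, ...) {
  cat(sprintf("<methnet_perturb> %d guide-gene tests; %d/%d regions validated at FDR %.2g\n",
              nrow(x$effects), x$n_validated, nrow(x$regions), x$fdr))
  invisible(x)
}

#' Permutation null for the validated-region count
#'
#' Shuffles the rows of the design matrix independently for each column
#' (preserving every guide's cell count), refits the deconvolution and
#' records the validated-region count, giving an empirical null that
#' controls for each guide's cell base. The empirical p-value uses the
#' add-one correction, so it is never zero.
#'
#' @inheritParams deconvolve_effects
#' @param n_reps Number of permutations (default 1000; fewer than 100 gives
#'   an unstable p floor and warns).
#' @param seed Seed for the permutations.
#' @return Object of class `methnet_bootstrap`: list with `observed`,
#'   `null_counts`, `n_reps`, `empirical_p`.
#' @export
bootstrap_validation_null <- function(log_counts, X, guide_meta,
                                      predicted_targets, n_reps = 1000,
                                      seed = 1, min_cells = 5, fdr = 0.05) {
  if (n_reps < 100) warn("fewer than 100 permutations: empirical p floor is coarse")
  obs <- deconvolve_effects(log_counts, X, guide_meta, predicted_targets,
                            min_cells = min_cells, fdr = fdr)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_reps), function(r) {
    Xp <- apply(X, 2, sample)
    dimnames(Xp) <- dimnames(X)
    suppressWarnings(
      deconvolve_effects(log_counts, Xp, guide_meta, predicted_targets,
                         min_cells = min_cells, fdr = fdr)$n_validated
    )
  }, integer(1))
  structure(list(observed = obs$n_validated, null_counts = null_counts,
                 n_reps = n_reps,
                 empirical_p = (1 + sum(null_counts >= obs$n_validated)) /
                   (1 + n_reps)),
            class = "methnet_bootstrap")
}

#' @export
print.methnet_bootstrap <- function(x, ...) {
  cat(sprintf("<methnet_bootstrap> observed %d validated regions; empirical p = %.4g (%d reps)\n",
              x$observed, x$empirical_p, x$n_reps))
  invisible(x)
}
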