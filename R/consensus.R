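#' Aggregate per-context networks into a consensus network
#'
#' For every (gene, cluster) pair with a nonzero coefficient in at least one
#' context, the consensus coefficient is the mean of the per-context
#' coefficients over all contexts where the gene was modeled (zero
#' coefficients included), weighted by each context model's cross-validated
#' R-squared floored at zero. Negative consensus coefficients are classed
#' activating (methylation gain lowers expression), positive repressing.
#'
#' @param context_networks List of `methnet_context_network` objects from
#'   [fit_contexts()].
#' @param network `methnet_network` with the candidate edges (supplies the
#'   signed distance `d` and the gene-body flag).
#' @return Tibble with `gene_id`, `cluster_id`, `coefficient`, `robustness`
#'   (number of contexts with a nonzero coefficient), `sign_class`, `d`,
#'   `in_gene_body`. Pairs whose weighted mean cancels to exactly zero are
#'   dropped (they carry no direction).
#' @export
build_consensus <- function(context_networks, network) {
  stopifnot(length(context_networks) >= 1)
  modeled <- map(context_networks, function(cn) {
    mutate(cn$models, context = cn$context)
  }) |> list_rbind()
  edges <- map(context_networks, function(cn) {
    if (nrow(cn$edges) == 0) return(NULL)
    mutate(cn$edges, context = cn$context)
  }) |> list_rbind()
  if (is.null(edges) || nrow(edges) == 0) {
    warn("no nonzero coefficients in any context")
    return(tibble(gene_id = character(), cluster_id = character(),
                  coefficient = numeric(), robustness = integer(),
                  sign_class = character(), d = numeric(),
                  in_gene_body = logical()))
  }
  pairs <- distinct(edges, .data$gene_id, .data$cluster_id)
  full <- pairs |>
    inner_join(select(modeled, "gene_id", "context", "r2"),
               by = "gene_id", relationship = "many-to-many") |>
    left_join(edges, by = c("gene_id", "cluster_id", "context")) |>
    mutate(coefficient = replace_na(.data$coefficient, 0),
           w = pmax(.data$r2, 0))
  zero_w <- full |>
    group_by(.data$gene_id) |>
    summarise(allzero = sum(.data$w) == 0, .groups = "drop") |>
    filter(.data$allzero)
  if (nrow(zero_w) > 0) {
    warn(sprintf("all context weights zero for %d gene(s); using unweighted mean",
                 nrow(zero_w)))
  }
  cons <- full |>
    group_by(.data$gene_id, .data$cluster_id) |>
    summarise(robustness = sum(.data$coefficient != 0),
              coefficient = if (sum(.data$w) > 0) {
                sum(.data$w * .data$coefficient) / sum(.data$w)
              } else mean(.data$coefficient),
              .groups = "drop") |>
    filter(.data$coefficient != 0) |>
    mutate(sign_class = ifelse(.data$coefficient < 0, "activating", "repressing")) |>
    left_join(network$edges, by = c("gene_id", "cluster_id")) |>
    arrange(.data$gene_id, .data$cluster_id)
  cons
}

#' Score consensus associations against the uniform-neighbourhood baseline
#'
#' The association score is `b_gc = log(|beta_gc| / sum_c' |beta_gc'|) +
#' log(k_g)` (natural log), where the denominator runs over the gene's
#' retained consensus edges and `k_g` is the full candidate-neighbourhood
#' size. It measures the information gain of the fitted network over a naive
#' model in which all `k_g` neighbours contribute equally `1/k_g`; a gene
#' whose retained coefficients are all equal in magnitude and whose retained
#' set spans the whole neighbourhood scores exactly zero. For every gene,
#' `sum_c exp(b_gc) = k_g` over retained edges.
#'
#' @param consensus Consensus edge tibble from [build_consensus()].
#' @param network `methnet_network` supplying `k_g`.
#' @return The consensus tibble with an added `score` column.
#' @export
association_score <- function(consensus, network) {
  scored <- consensus |>
    inner_join(network$k, by = "gene_id") |>
    group_by(.data$gene_id) |>
    mutate(score = log(abs(.data$coefficient) / sum(abs(.data$coefficient))) +
             log(.data$k)) |>
    ungroup()
  stopifnot(all(is.finite(scored$score)))
  scored
}

#' Fit the distance trend of association scores
#'
#' Penalized univariate spline (additive-model smooth, smoothing selected by
#' generalized cross-validation) of the score on the absolute TSS-cluster
#' distance. Distance acts on associations in an element-agnostic way; the
#' residual `b_gc - f(|d_gc|)` isolates the element-intrinsic part of the
#' score. With a degenerate distance spread the trend collapses to the mean.
#'
#' @param scored Scored edge tibble from [association_score()].
#' @param k Spline basis dimension upper bound (default 10).
#' @return Object of class `methnet_distance_trend`; use [predict()] or
#'   [adjust_scores()] to evaluate it.
#' @export
fit_distance_trend <- function(scored, k = 10) {
  if (nrow(scored) < 50) {
    warn(sprintf("fitting distance trend on only %d edges", nrow(scored)))
  }
  df <- tibble(score = scored$score, abs_d = abs(scored$d))
  nu <- n_distinct(df$abs_d)
  if (nu < 4) {
    return(structure(list(constant = mean(df$score), model = NULL),
                     class = "methnet_distance_trend"))
  }
  kk <- min(k, nu - 1)
  model <- mgcv::gam(score ~ s(abs_d, k = kk), data = df, method = "GCV.Cp")
  structure(list(constant = NULL, model = model),
            class = "methnet_distance_trend")
}

#' @export
predict.methnet_distance_trend <- function(object, abs_d, ...) {
  if (!is.null(object$constant)) return(rep(object$constant, length(abs_d)))
  as.numeric(predict(object$model, newdata = data.frame(abs_d = abs_d)))
}

#' @export
print.methnet_distance_trend <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<methnet_distance_trend> constant (%.4g)\n", x$constant))
  } else {
    cat(sprintf("<methnet_distance_trend> spline on %d edges, edf %.2f\n",
                length(x$model$y), sum(x$model$edf)))
  }
  invisible(x)
}

#' Remove the distance trend from association scores
#'
#' @param scored Scored edge tibble from [association_score()].
#' @param trend `methnet_distance_trend` from [fit_distance_trend()].
#' @return The tibble with an added `adjusted_score = score - f(|d|)` column.
#' @export
adjust_scores <- function(scored, trend) {
  mutate(scored, adjusted_score = .data$score - predict(trend, abs(.data$d)))
}

#' Sum adjusted scores into per-cluster regulatory potential
#'
#' The potential of a cluster is the sum of its associations'
#' distance-adjusted scores; clusters with no retained association get
#' potential zero, so the total potential is conserved and equals the sum of
#' all adjusted scores.
#'
#' @param adjusted Edge tibble from [adjust_scores()].
#' @param clusters Optional cluster tibble; when given, clusters without
#'   edges are included with potential 0.
#' @param cluster_betas Optional cluster-by-sample beta matrix used to
#'   report each cluster's methylation variance across all samples.
#' @return Tibble with `cluster_id`, `potential`, `methylation_variance`.
#' @export
regulatory_potential <- function(adjusted, clusters = NULL, cluster_betas = NULL) {
  pot <- adjusted |>
    group_by(.data$cluster_id) |>
    summarise(potential = sum(.data$adjusted_score), .groups = "drop")
  if (!is.null(clusters)) {
    pot <- pot |>
      right_join(tibble(cluster_id = clusters$cluster_id), by = "cluster_id") |>
      mutate(potential = replace_na(.data$potential, 0))
  }
  mv <- if (!is.null(cluster_betas)) {
    mu <- rowMeans(cluster_betas, na.rm = TRUE)
    v <- rowMeans((cluster_betas - mu)^2, na.rm = TRUE)
    tibble(cluster_id = rownames(cluster_betas), methylation_variance = v)
  } else tibble(cluster_id = character(), methylation_variance = numeric())
  pot |>
    left_join(mv, by = "cluster_id") |>
    arrange(desc(.data$potential))
}

#' Call regulatory hubs with an iterated elbow rule
#'
#' Potentials are sorted in decreasing order and the elbow of the resulting
#' curve is located with an iterated chord rule: starting from the chord
#' joining the first and last point, the rank maximizing the (vertical,
#' hence perpendicular-equivalent) deviation below the chord becomes the new
#' right anchor, and the chord is re-anchored until the elbow index
#' stabilizes. The refinement homes in on the sharpest bend near the top of
#' the curve and, on a curve with a clean two-population break, converges to
#' the boundary exactly. The hub threshold is the potential at the last rank
#' before the converged elbow; `is_hub` is `potential >= threshold`. Ties
#' are broken toward the smaller hub set. A curve with no bend (all equal,
#' or a straight ramp) is flagged degenerate: all-equal potentials yield no
#' hubs with a warning, a ramp yields at most one.
#'
#' @param potentials Tibble from [regulatory_potential()].
#' @return The tibble with an `is_hub` column, carrying attributes
#'   `elbow_threshold`, `elbow_rank` and `degenerate`.
#' @export
call_hubs <- function(potentials) {
  p <- sort(potentials$potential, decreasing = TRUE)
  n <- length(p)
  if (sum(p > 0) < 10) {
    warn("fewer than 10 clusters with positive potential; elbow may be unstable")
  }
  rng <- p[1] - p[n]
  if (rng == 0) {
    warn("all potentials equal; no hubs called")
    out <- mutate(potentials, is_hub = FALSE)
    attr(out, "elbow_threshold") <- Inf
    attr(out, "elbow_rank") <- NA_integer_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  degenerate <- FALSE
  e <- n
  repeat {
    xs <- seq_len(e)
    chord <- p[1] + (p[e] - p[1]) * (xs - 1) / max(e - 1, 1)
    dev <- chord - p[xs]
    if (max(dev) <= 1e-8 * rng) {
      if (e == n) degenerate <- TRUE  # no bend at all: flat curve or ramp
      break
    }
    r <- which.max(dev)
    if (r <= 1 || r == e) break
    e <- r
  }
  if (degenerate) {
    elbow <- 1L
    threshold <- p[1]
  } else {
    elbow <- e
    threshold <- p[max(elbow - 1, 1)]
  }
  out <- mutate(potentials, is_hub = .data$potential >= threshold)
  attr(out, "elbow_threshold") <- threshold
  attr(out, "elbow_rank") <- elbow
  attr(out, "degenerate") <- degenerate
  out
}

#' Threshold and degeneracy of a hub call
#' @param potentials Result of [call_hubs()].
#' @return One-row tibble with `elbow_threshold`, `elbow_rank`, `n_hubs`,
#'   `degenerate`.
#' @export
hub_call_summary <- function(potentials) {
  tibble(elbow_threshold = attr(potentials, "elbow_threshold"),
         elbow_rank = attr(potentials, "elbow_rank"),
         n_hubs = sum(potentials$is_hub),
         degenerate = attr(potentials, "degenerate"))
}
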