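#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname methnet_tidiers
tidy.methnet_gene_model <- function(x, ...) {
  mutate(x$coef, gene_id = x$gene_id, context = x$context, .before = 1)
}

#' Tidiers for fitted methnet objects
#'
#' [tidy()] returns the per-term (edge, effect or curve-point) table of a
#' fitted object; [glance()] returns a one-row model summary.
#'
#' @param x A fitted methnet object.
#' @param ... Unused.
#' @return A tibble.
#' @name methnet_tidiers
NULL

#' @export
#' @rdname methnet_tidiers
glance.methnet_gene_model <- function(x, ...) {
  tibble(gene_id = x$gene_id, context = x$context, n_nonzero = nrow(x$coef),
         lambda = x$lambda, alpha = x$alpha, r2 = x$r2,
         n_samples = x$n_samples)
}

#' @export
#' @rdname methnet_tidiers
tidy.methnet_context_network <- function(x, ...) {
  mutate(x$edges, context = x$context, .before = 1)
}

#' @export
#' @rdname methnet_tidiers
glance.methnet_context_network <- function(x, ...) {
  tibble(context = x$context, n_edges = nrow(x$edges),
         n_genes_modeled = nrow(x$models),
         median_r2 = stats::median(x$models$r2))
}

#' @export
#' @rdname methnet_tidiers
tidy.methnet_perturb <- function(x, ...) x$effects

#' @export
#' @rdname methnet_tidiers
glance.methnet_perturb <- function(x, ...) {
  tibble(n_tests = nrow(x$effects), n_regions = nrow(x$regions),
         n_validated = x$n_validated, fdr = x$fdr)
}

#' @export
#' @rdname methnet_tidiers
tidy.methnet_bootstrap <- function(x, ...) {
  tibble(rep = seq_along(x$null_counts), validated = x$null_counts)
}

#' @export
#' @rdname methnet_tidiers
glance.methnet_bootstrap <- function(x, ...) {
  tibble(observed = x$observed, n_reps = x$n_reps,
         null_mean = mean(x$null_counts), empirical_p = x$empirical_p)
}
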