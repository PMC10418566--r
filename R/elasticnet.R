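#' Filter genes by expression variability
#'
#' Keeps genes whose per-context population (n-denominator) standard
#' deviation of log-normalized expression is at least `sd_min`; the quoted
#' rule removes genes with "standard deviation less than 1", so a gene at
#' exactly `sd_min` is retained.
#'
#' @param expression Gene-by-sample numeric matrix (log-normalized).
#' @param sd_min Minimum standard deviation (default 1).
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(expression, sd_min = 1) {
  sds <- row_pop_sd(expression)
  rownames(expression)[!is.na(sds) & sds >= sd_min]
}

#' Fit one gene's penalized methylation model
#'
#' Elastic-net regression of a gene's expression on the beta values of its
#' candidate neighbour clusters plus unpenalized sample-type covariates:
#' `y = beta0(z) + sum_c beta_c x_c + eps` with penalty
#' `lambda * (alpha * sum|beta_c| + (1 - alpha) * sum beta_c^2)`.
#' The mixing parameter `alpha` is chosen by minimum mean cross-validation
#' error over `alpha_grid`; within the winning path, `lambda` follows
#' `lambda_rule` (default the one-standard-error rule, which controls the
#' false-positive edges that propagate into the consensus network;
#' `"min"` gives the minimum-CV-error fit).
#'
#' By default the fit is relaxed (`relax = TRUE`): alongside the penalized
#' path, cross-validation also scores the least-squares refit on each
#' active set (glmnet's relaxation with `gamma = c(0, 1)`) and the
#' one-standard-error rule picks between them. CV-based penalty selection
#' alone is known to over-select; letting the unpenalized refit compete in
#' CV removes most spurious neighbours while keeping the strong ones, and
#' debiases the retained coefficients. Set `relax = FALSE` for the plain
#' elastic-net solution (which satisfies the elastic-net KKT conditions at
#' the selected penalty).
#'
#' Predictors are standardized internally; coefficients are reported on the
#' original beta-value scale. Fold assignment is seeded deterministically
#' from `seed` and the gene/context labels, so results are order-invariant
#' and reproducible.
#'
#' @param y Numeric expression vector over samples.
#' @param X Sample-by-cluster numeric matrix of neighbourhood beta values
#'   (0 columns allowed: intercept-only model).
#' @param z Optional factor of sample types; "normal" is used as the
#'   reference level when present. A single-level factor is ignored.
#' @param gene_id,context Identifiers, used for bookkeeping and fold seeding.
#' @param cv_folds Number of CV folds (default 10); reduced with a warning
#'   when there are fewer samples than folds.
#' @param alpha_grid Grid of elastic-net mixing values.
#' @param seed Base seed for fold assignment.
#' @param lambda_rule `"1se"` or `"min"`.
#' @param relax Cross-validate the active-set least-squares refit alongside
#'   the penalized path (default `TRUE`).
#' @param nlambda Length of the penalty path (default 50).
#' @return Object of class `methnet_gene_model`: list with `gene_id`,
#'   `context`, `beta0` (named per-level intercepts), `coef` (tibble of
#'   nonzero cluster coefficients), `lambda`, `alpha`, `gamma` (relaxation
#'   mixing actually selected; 1 when `relax = FALSE`), `r2`
#'   (cross-validated `1 - CV-MSE/Var(y)`), `n_samples`.
#' @export
fit_gene_model <- function(y, X, z = NULL, gene_id = "gene", context = "all",
                           cv_folds = 10, alpha_grid = seq(0.1, 1, by = 0.1),
                           seed = 1, lambda_rule = c("1se", "min"),
                           relax = TRUE, nlambda = 50) {
  lambda_rule <- match.arg(lambda_rule)
  n <- length(y)
  if (!is.null(dim(X)) && nrow(X) != n) abort("rows of X must align with y")
  z <- normalize_sample_type(z)
  Z <- if (!is.null(z) && nlevels(z) > 1) {
    model.matrix(~z)[, -1, drop = FALSE]
  } else NULL

  nfolds <- cv_folds
  if (n < cv_folds) {
    nfolds <- max(3, floor(n / 2))
    warn(sprintf("%s/%s: %d samples < %d folds, reducing to %d folds",
                 gene_id, context, n, cv_folds, nfolds))
  }
  p <- if (is.null(dim(X))) 0L else ncol(X)

  if (p == 0L) {
    return(intercept_only_model(y, z, gene_id, context, nfolds, seed))
  }

  # glmnet needs >= 2 penalized columns; pad with a constant dummy
  Xp <- X
  padded <- FALSE
  if (p == 1L) {
    Xp <- cbind(X, `.pad` = 0)
    padded <- TRUE
  }
  design <- cbind(Z, Xp)
  pf <- c(rep(0, if (is.null(Z)) 0 else ncol(Z)), rep(1, ncol(Xp)))

  set.seed(seed_for(seed, paste(gene_id, context)))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))

  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(design, y, alpha = a, foldid = foldid,
                            penalty.factor = pf, standardize = TRUE,
                            relax = relax, gamma = if (relax) c(0, 1),
                            nlambda = nlambda, thresh = 1e-10)
    m <- if (relax) {
      min(vapply(cv$relaxed$statlist, function(s) min(s$cvm), numeric(1)))
    } else min(cv$cvm)
    if (is.null(best) || m < best$m) best <- list(m = m, cv = cv, alpha = a)
  }
  cv <- best$cv
  if (relax) {
    which_rule <- if (lambda_rule == "1se") "1se" else "min"
    lambda <- cv$relaxed[[paste0("lambda.", which_rule)]]
    gamma_sel <- cv$relaxed[[paste0("gamma.", which_rule)]]
    stat <- cv$relaxed$statlist[[paste0("g:", gamma_sel)]]
    cvm_sel <- stat$cvm[which.min(abs(stat$lambda - lambda))]
    co <- as.matrix(coef(cv, s = lambda, gamma = gamma_sel))[, 1]
  } else {
    lambda <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
    gamma_sel <- 1
    cvm_sel <- cv$cvm[which(cv$lambda == lambda)[1]]
    co <- as.matrix(coef(cv, s = lambda))[, 1]
  }
  r2 <- 1 - cvm_sel / pop_var(y)
  nz_off <- 1 + (if (is.null(Z)) 0 else ncol(Z))
  cluster_co <- co[-seq_len(nz_off)]
  if (padded) cluster_co <- cluster_co[names(cluster_co) != ".pad"]
  nz <- cluster_co[cluster_co != 0]

  beta0 <- build_beta0(co[1], if (is.null(Z)) NULL else co[1 + seq_len(ncol(Z))], z)
  structure(list(gene_id = gene_id, context = context, beta0 = beta0,
                 coef = tibble(cluster_id = names(nz), coefficient = unname(nz)),
                 lambda = lambda, alpha = best$alpha, gamma = gamma_sel,
                 r2 = r2, n_samples = n, nfolds = nfolds),
            class = "methnet_gene_model")
}

normalize_sample_type <- function(z) {
  if (is.null(z)) return(NULL)
  z <- as.factor(z)
  if ("normal" %in% levels(z)) z <- stats::relevel(z, ref = "normal")
  z
}

build_beta0 <- function(intercept, zco, z) {
  if (is.null(z) || nlevels(z) <= 1) return(c("(all)" = unname(intercept)))
  out <- setNames(rep(unname(intercept), nlevels(z)), levels(z))
  out[-1] <- out[-1] + unname(zco)
  out
}

# covariate-only model for genes with an empty candidate neighbourhood
intercept_only_model <- function(y, z, gene_id, context, nfolds, seed) {
  n <- length(y)
  df <- if (is.null(z) || nlevels(z) <= 1) {
    data.frame(y = y)
  } else data.frame(y = y, z = z)
  fit <- lm(y ~ ., data = df)
  set.seed(seed_for(seed, paste(gene_id, context)))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    m <- lm(y ~ ., data = df[tr, , drop = FALSE])
    pred[!tr] <- predict(m, newdata = df[!tr, , drop = FALSE])
  }
  r2 <- 1 - mean((y - pred)^2) / pop_var(y)
  co <- coef(fit)
  beta0 <- build_beta0(co[1], if (length(co) > 1) co[-1] else NULL, z)
  structure(list(gene_id = gene_id, context = context, beta0 = beta0,
                 coef = tibble(cluster_id = character(), coefficient = numeric()),
                 lambda = Inf, alpha = NA_real_, gamma = NA_real_, r2 = r2,
                 n_samples = n, nfolds = nfolds),
            class = "methnet_gene_model")
}

#' @export
print.methnet_gene_model <- function(x, ...) {
  cat(sprintf("<methnet_gene_model> %s [%s]: %d nonzero of candidates, R2=%.3f (lambda=%.4g, alpha=%.2g)\n",
              x$gene_id, x$context, nrow(x$coef), x$r2, x$lambda, x$alpha))
  invisible(x)
}

#' Fit all gene models for one context
#'
#' Applies the variability filter, drops methylation cluster rows with more
#' than `max_missing` missingness across the context's samples, mean-imputes
#' the remaining missing cells per cluster, and fits [fit_gene_model()] for
#' every surviving gene. Genes are fitted independently, so results do not
#' depend on gene order.
#'
#' @param expression Gene-by-sample matrix (log-normalized).
#' @param cluster_betas Cluster-by-sample beta matrix.
#' @param network `methnet_network` from [build_candidate_network()].
#' @param samples Sample tibble (`sample_id`, `context`, `sample_type`).
#' @param context Context label to fit.
#' @param sd_min,cv_folds,alpha_grid,seed,lambda_rule Passed to the filters
#'   and [fit_gene_model()].
#' @param max_missing Maximum tolerated fraction of missing betas per
#'   cluster row (default 0.2).
#' @return Object of class `methnet_context_network`: list with `context`,
#'   `edges` (tibble `gene_id`, `cluster_id`, `coefficient`, all nonzero)
#'   and `models` (tibble `gene_id`, `lambda`, `alpha`, `r2`, `n_samples`).
#' @export
fit_context <- function(expression, cluster_betas, network, samples, context,
                        sd_min = 1, cv_folds = 10,
                        alpha_grid = seq(0.1, 1, by = 0.1), seed = 1,
                        lambda_rule = c("1se", "min"), max_missing = 0.2,
                        relax = TRUE, nlambda = 50) {
  lambda_rule <- match.arg(lambda_rule)
  ids <- intersect(samples$sample_id[samples$context == context],
                   colnames(expression))
  empty <- structure(list(context = context,
                          edges = tibble(gene_id = character(),
                                         cluster_id = character(),
                                         coefficient = numeric()),
                          models = tibble(gene_id = character(),
                                          lambda = numeric(), alpha = numeric(),
                                          r2 = numeric(), n_samples = integer())),
                     class = "methnet_context_network")
  if (length(ids) < 10) {
    warn(sprintf("context %s has %d samples (< 10), skipped", context, length(ids)))
    return(empty)
  }
  E <- expression[, ids, drop = FALSE]
  M <- cluster_betas[, ids, drop = FALSE]
  na_frac <- rowMeans(is.na(M))
  M <- M[na_frac <= max_missing, , drop = FALSE]
  if (anyNA(M)) {
    mu <- rowMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 1]]
  }
  st <- samples$sample_type[match(ids, samples$sample_id)]
  z <- if (length(unique(st)) > 1) factor(st) else NULL

  genes_keep <- intersect(filter_genes(E, sd_min), network$k$gene_id)
  if (length(genes_keep) == 0) {
    warn(sprintf("context %s: no genes pass the sd filter", context))
    return(empty)
  }
  nbrs <- split(network$edges$cluster_id, network$edges$gene_id)
  models <- map(genes_keep, function(g) {
    cl <- intersect(nbrs[[g]] %||% character(), rownames(M))
    X <- t(M[cl, , drop = FALSE])
    fit_gene_model(E[g, ], X, z = z, gene_id = g, context = context,
                   cv_folds = cv_folds, alpha_grid = alpha_grid,
                   seed = seed, lambda_rule = lambda_rule,
                   relax = relax, nlambda = nlambda)
  })
  edges <- map(models, function(m) {
    if (nrow(m$coef) == 0) return(NULL)
    mutate(m$coef, gene_id = m$gene_id, .before = 1)
  }) |> list_rbind()
  if (nrow(edges) > 0) edges <- select(edges, "gene_id", "cluster_id", "coefficient")
  meta <- map(models, function(m) {
    tibble(gene_id = m$gene_id, lambda = m$lambda, alpha = m$alpha,
           gamma = m$gamma, r2 = m$r2, n_samples = m$n_samples)
  }) |> list_rbind()
  structure(list(context = context, edges = edges, models = meta),
            class = "methnet_context_network")
}

#' @export
print.methnet_context_network <- function(x, ...) {
  cat(sprintf("<methnet_context_network> %s: %d edges over %d modeled genes\n",
              x$context, nrow(x$edges), nrow(x$models)))
  invisible(x)
}

#' Fit per-context networks for every context
#'
#' @inheritParams fit_context
#' @param contexts Contexts to fit (default: all contexts present in
#'   `samples`).
#' @param ... Passed to [fit_context()].
#' @return Named list of `methnet_context_network` objects.
#' @export
fit_contexts <- function(expression, cluster_betas, network, samples,
                         contexts = NULL, seed = 1, ...) {
  contexts <- contexts %||% sort(unique(samples$context))
  out <- map(contexts, function(ctx) {
    fit_context(expression, cluster_betas, network, samples, ctx,
                seed = seed_for(seed, ctx), ...)
  })
  setNames(out, contexts)
}
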