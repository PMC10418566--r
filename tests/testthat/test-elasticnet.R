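# naive coordinate-descent reference for the elastic net on the
# standardized scale: objective 1/(2n)*RSS + lambda*(alpha*|b| + (1-alpha)/2*b^2)
cd_reference <- function(X, y, lambda, alpha, iters = 5000, tol = 1e-12) {
  n <- nrow(X)
  mx <- colMeans(X)
  sx <- sqrt(colMeans(scale(X, center = TRUE, scale = FALSE)^2))
  Xs <- scale(X, center = mx, scale = sx)
  my <- mean(y)
  ys <- y - my
  b <- rep(0, ncol(X))
  for (it in seq_len(iters)) {
    b_old <- b
    for (j in seq_len(ncol(X))) {
      r <- ys - Xs[, -j, drop = FALSE] %*% b[-j]
      rho <- mean(Xs[, j] * r)
      b[j] <- sign(rho) * max(abs(rho) - lambda * alpha, 0) /
        (1 + lambda * (1 - alpha))
    }
    if (max(abs(b - b_old)) < tol) break
  }
  beta <- b / sx
  c(intercept = my - sum(beta * mx), beta)
}

test_that("the sd filter uses population sd with an inclusive boundary", {
  n <- 50
  flat <- rep(3, n)
  exact <- rep(c(2, 4), n / 2)            # population sd exactly 1
  wide <- rep(c(0, 4), n / 2)
  m <- rbind(flat = flat, exact = exact, wide = wide)
  colnames(m) <- paste0("s", 1:n)
  expect_setequal(filter_genes(m, sd_min = 1), c("exact", "wide"))
})

test_that("the sd filter matches direct computation on planted variance", {
  set.seed(13)
  m <- rbind(matrix(rnorm(30 * 100, sd = 2), 30),
             matrix(rnorm(70 * 100, sd = 0.3), 70))
  rownames(m) <- sprintf("g%03d", 1:100)
  colnames(m) <- sprintf("s%03d", 1:100)
  keep <- filter_genes(m)
  direct <- rownames(m)[sqrt(rowMeans((m - rowMeans(m))^2)) >= 1]
  expect_identical(keep, direct)
  expect_setequal(keep, sprintf("g%03d", 1:30))
})

test_that("a noiseless single-predictor gene is recovered essentially exactly", {
  set.seed(3)
  x <- matrix(runif(100), 100, 1, dimnames = list(NULL, "c1"))
  y <- as.vector(2 * x)
  m <- fit_gene_model(y, x, gene_id = "g", seed = 1)
  expect_equal(m$coef$cluster_id, "c1")
  expect_equal(m$coef$coefficient, 2, tolerance = 1e-6)
  expect_gt(m$r2, 0.999)
})

test_that("an empty neighbourhood yields the covariate group means", {
  set.seed(4)
  z <- factor(rep(c("normal", "tumor"), each = 40))
  y <- rnorm(80, mean = ifelse(z == "tumor", 6, 5))
  m <- fit_gene_model(y, matrix(nrow = 80, ncol = 0), z = z, gene_id = "g")
  expect_equal(nrow(m$coef), 0)
  expect_equal(unname(m$beta0["normal"]), mean(y[z == "normal"]), tolerance = 1e-10)
  expect_equal(unname(m$beta0["tumor"]), mean(y[z == "tumor"]), tolerance = 1e-10)
})

test_that("planted effects are recovered with few false positives", {
  set.seed(5)
  n <- 200; p <- 30
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, sprintf("c%02d", 1:p)))
  beta <- numeric(p); beta[c(3, 11, 27)] <- c(1, -1, 1)
  y <- as.vector(X %*% beta) + rnorm(n, 0, 0.5)
  m <- fit_gene_model(y, X, gene_id = "g", seed = 2)
  expect_true(all(sprintf("c%02d", c(3, 11, 27)) %in% m$coef$cluster_id))
  expect_lte(nrow(m$coef) - 3, 3)
})

test_that("the plain elastic-net mode matches a coordinate-descent reference", {
  set.seed(6)
  n <- 120; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("c", 1:p)))
  y <- X[, 2] * 1.5 - X[, 5] + rnorm(n, 0, 0.4)
  m <- fit_gene_model(y, X, gene_id = "g", seed = 3, relax = FALSE)
  ref <- cd_reference(X, y, lambda = m$lambda, alpha = m$alpha)
  got <- setNames(rep(0, p), paste0("c", 1:p))
  got[m$coef$cluster_id] <- m$coef$coefficient
  expect_equal(unname(got), unname(ref[-1]), tolerance = 1e-4)
})

test_that("the plain elastic-net solution satisfies the KKT conditions", {
  set.seed(7)
  n <- 150; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("c", 1:p)))
  y <- X[, 1] - 0.8 * X[, 4] + rnorm(n, 0, 0.5)
  m <- fit_gene_model(y, X, gene_id = "g", seed = 4, relax = FALSE)
  # re-express on the standardized scale glmnet penalizes on
  mx <- colMeans(X)
  sx <- sqrt(colMeans(scale(X, center = TRUE, scale = FALSE)^2))
  Xs <- scale(X, center = mx, scale = sx)
  beta <- setNames(rep(0, p), paste0("c", 1:p))
  beta[m$coef$cluster_id] <- m$coef$coefficient
  bs <- beta * sx
  b0 <- mean(y) - sum(bs * colMeans(Xs))
  r <- y - b0 - as.vector(Xs %*% bs)
  grad <- colMeans(Xs * r) - m$lambda * (1 - m$alpha) * bs
  tol <- 1e-6 * max(1, m$lambda)
  for (j in seq_len(p)) {
    if (bs[j] != 0) {
      expect_lt(abs(grad[j] - m$lambda * m$alpha * sign(bs[j])), tol)
    } else {
      expect_lte(abs(grad[j]), m$lambda * m$alpha + tol)
    }
  }
})

test_that("fits are reproducible under the same seed and fold counts shrink with n", {
  set.seed(8)
  X <- matrix(runif(40 * 3), 40, 3, dimnames = list(NULL, paste0("c", 1:3)))
  y <- X[, 1] * 2 + rnorm(40, 0, 0.3)
  expect_warning(m1 <- fit_gene_model(y[1:8], X[1:8, ], gene_id = "g", seed = 9),
                 "folds")
  m2 <- fit_gene_model(y, X, gene_id = "g", seed = 10)
  m3 <- fit_gene_model(y, X, gene_id = "g", seed = 10)
  expect_equal(m2$coef, m3$coef)
  expect_equal(m2$lambda, m3$lambda)
})

test_that("a pure-noise gene has near-zero cross-validated R2", {
  set.seed(10)
  r2s <- replicate(5, {
    X <- matrix(runif(150 * 10), 150, 10, dimnames = list(NULL, paste0("c", 1:10)))
    y <- rnorm(150)
    fit_gene_model(y, X, gene_id = "g", seed = sample(1e4, 1))$r2
  })
  expect_lte(mean(r2s), 0.1)
})

small_context_fixture <- function(seed = 1) {
  genome <- make_toy_genome(n_genes = 6, n_probes = 60, n_gene_clumps = 1,
                            seed = seed)
  clusters <- cluster_probes(genome$probes)
  network <- build_candidate_network(genome$genes, clusters)
  truth <- plant_truth(network, clusters, genome$genes, n_hubs = 1,
                       hub_targets = 2, seed = seed)
  sim <- simulate_expression_methylation(truth, genome$genes, clusters,
                                         n_contexts = 2,
                                         n_samples_per_context = 60,
                                         seed = seed + 1)
  cb <- average_cluster_beta(sim$methylation, clusters)
  list(genome = genome, clusters = clusters, network = network,
       truth = truth, sim = sim, cb = cb)
}

test_that("genes failing the sd filter in a context are absent from that context", {
  f <- small_context_fixture(seed = 2)
  g <- f$genome$genes$gene_id[1]
  expr <- f$sim$expression
  ids_a <- f$sim$samples$sample_id[f$sim$samples$context == "CTX1"]
  expr[g, ids_a] <- mean(expr[g, ids_a])  # flat in CTX1 only
  nets <- suppressWarnings(
    fit_contexts(expr, f$cb, f$network, f$sim$samples, seed = 3)
  )
  expect_false(g %in% nets$CTX1$models$gene_id)
  expect_true(g %in% nets$CTX2$models$gene_id)
})

test_that("results do not depend on gene order within a context", {
  f <- small_context_fixture(seed = 4)
  expr <- f$sim$expression
  n1 <- suppressWarnings(fit_context(expr, f$cb, f$network, f$sim$samples,
                                     "CTX1", seed = 5))
  perm <- expr[rev(rownames(expr)), ]
  n2 <- suppressWarnings(fit_context(perm, f$cb, f$network, f$sim$samples,
                                     "CTX1", seed = 5))
  key <- function(cn) {
    e <- cn$edges[order(cn$edges$gene_id, cn$edges$cluster_id), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(n1), key(n2))
})

test_that("a context with too few samples is skipped with a warning", {
  f <- small_context_fixture(seed = 6)
  few <- f$sim$samples[1:5, ]
  expect_warning(cn <- fit_context(f$sim$expression, f$cb, f$network, few,
                                   "CTX1", seed = 1), "skipped")
  expect_equal(nrow(cn$edges), 0)
})

test_that("high-missingness clusters are dropped and the rest mean-imputed", {
  f <- small_context_fixture(seed = 7)
  cb <- f$cb
  ids <- f$sim$samples$sample_id[f$sim$samples$context == "CTX1"]
  cb[1, ids[1:40]] <- NA                       # > 20% missing: dropped
  cb[2, ids[1:5]] <- NA                        # < 20%: imputed
  cn <- suppressWarnings(fit_context(f$sim$expression, cb, f$network,
                                     f$sim$samples, "CTX1", seed = 8))
  expect_false(rownames(cb)[1] %in% cn$edges$cluster_id)
})
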