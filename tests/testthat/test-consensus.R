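two_ctx <- function() {
  net <- make_net(
    edges = tibble::tibble(gene_id = "g1", cluster_id = c("c1", "c2"),
                           d = c(-5e4, 2e5), in_gene_body = FALSE),
    k = tibble::tibble(gene_id = "g1", k = 2L)
  )
  cn1 <- make_ctx("A",
                  tibble::tibble(gene_id = "g1", cluster_id = "c1", coefficient = 0.4),
                  tibble::tibble(gene_id = "g1", lambda = 0.1, alpha = 1, r2 = 0.5,
                                 n_samples = 100L))
  cn2 <- make_ctx("B",
                  tibble::tibble(gene_id = character(), cluster_id = character(),
                                 coefficient = numeric()),
                  tibble::tibble(gene_id = "g1", lambda = 0.1, alpha = 1, r2 = 0.5,
                                 n_samples = 100L))
  list(net = net, cn1 = cn1, cn2 = cn2)
}

test_that("consensus averages coefficients over modeled contexts, zeros included", {
  f <- two_ctx()
  cons <- build_consensus(list(f$cn1, f$cn2), f$net)
  # (0.5 * 0.4 + 0.5 * 0) / (0.5 + 0.5) = 0.2, nonzero in one context
  expect_equal(cons$coefficient, 0.2)
  expect_equal(cons$robustness, 1L)
  expect_equal(cons$sign_class, "repressing")
  expect_equal(cons$d, -5e4)
})

test_that("a single context passes through as the consensus", {
  f <- two_ctx()
  cons <- build_consensus(list(f$cn1), f$net)
  expect_equal(cons$coefficient, 0.4)
  expect_equal(cons$robustness, 1L)
})

test_that("context order does not change the consensus", {
  f <- two_ctx()
  a <- build_consensus(list(f$cn1, f$cn2), f$net)
  b <- build_consensus(list(f$cn2, f$cn1), f$net)
  expect_equal(a, b)
})

test_that("all-zero weights fall back to an unweighted mean with a warning", {
  f <- two_ctx()
  f$cn1$models$r2 <- -0.2
  f$cn2$models$r2 <- -0.1
  expect_warning(cons <- build_consensus(list(f$cn1, f$cn2), f$net),
                 "unweighted")
  expect_equal(cons$coefficient, 0.2)
})

test_that("negative consensus coefficients are activating", {
  f <- two_ctx()
  f$cn1$edges$coefficient <- -0.8
  cons <- build_consensus(list(f$cn1), f$net)
  expect_equal(cons$sign_class, "activating")
})

score_fixture <- function(betas, k) {
  n <- length(betas)
  net <- make_net(
    edges = tibble::tibble(gene_id = "g1",
                           cluster_id = paste0("c", seq_len(n)),
                           d = seq(1e4, by = 1e4, length.out = n),
                           in_gene_body = FALSE),
    k = tibble::tibble(gene_id = "g1", k = as.integer(k))
  )
  cons <- tibble::tibble(gene_id = "g1", cluster_id = paste0("c", seq_len(n)),
                         coefficient = betas, robustness = 1L,
                         sign_class = ifelse(betas < 0, "activating", "repressing"),
                         d = net$edges$d, in_gene_body = FALSE)
  list(net = net, cons = cons)
}

test_that("equal coefficients over the full neighbourhood score exactly zero", {
  f <- score_fixture(rep(0.3, 4), k = 4)
  scored <- association_score(f$cons, f$net)
  expect_equal(scored$score, rep(0, 4))
})

test_that("scores follow the log-ratio against the uniform baseline", {
  f <- score_fixture(c(0.9, -0.1), k = 2)
  scored <- association_score(f$cons, f$net)
  expect_equal(sort(scored$score), sort(log(c(1.8, 0.2))), tolerance = 1e-12)
})

test_that("exp(score) sums to k for every gene", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    f <- score_fixture(runif(n, -1, 1), k = n + sample(0:5, 1))
    f$cons <- f$cons[f$cons$coefficient != 0, ]
    scored <- association_score(f$cons, f$net)
    expect_equal(sum(exp(scored$score)), unique(scored$k), tolerance = 1e-12)
  }
})

test_that("the distance trend recovers a planted linear decay", {
  set.seed(1)
  n <- 2000
  d <- runif(n, 1e4, 1e6)
  scored <- tibble::tibble(score = -d / 1e6 + rnorm(n, 0, 0.1), d = d)
  trend <- fit_distance_trend(scored)
  grid <- quantile(d, probs = seq(0.05, 0.95, length.out = 50))
  expect_lt(max(abs(predict(trend, grid) - (-grid / 1e6))), 0.05)
  # residual mean vanishes on the training edges
  adj <- adjust_scores(scored, trend)
  expect_lt(abs(mean(adj$adjusted_score)), 1e-6)
})

test_that("a distance-free score yields an essentially constant trend", {
  set.seed(2)
  n <- 1000
  scored <- tibble::tibble(score = rnorm(n, 1.5, 0.1), d = runif(n, 1e4, 1e6))
  trend <- fit_distance_trend(scored)
  grid <- seq(2e4, 9.8e5, length.out = 50)
  expect_lt(max(abs(predict(trend, grid) - mean(scored$score))), 0.05)
})

test_that("degenerate distances collapse the trend to the mean", {
  scored <- tibble::tibble(score = c(1, 2, 3), d = rep(5e4, 3))
  trend <- suppressWarnings(fit_distance_trend(scored))
  expect_equal(predict(trend, c(5e4, 1e5)), c(2, 2))
})

test_that("potential sums adjusted scores per cluster and conserves the total", {
  adjusted <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    cluster_id = c("c1", "c1", "c2"),
    adjusted_score = c(1.2, -0.2, 0.7)
  )
  pot <- regulatory_potential(adjusted)
  expect_equal(pot$potential[pot$cluster_id == "c1"], 1.0)
  expect_equal(pot$potential[pot$cluster_id == "c2"], 0.7)
  expect_equal(sum(pot$potential), sum(adjusted$adjusted_score), tolerance = 1e-12)
})

test_that("clusters with no retained edges get potential zero", {
  adjusted <- tibble::tibble(gene_id = "g1", cluster_id = "c1", adjusted_score = 2)
  clusters <- tibble::tibble(cluster_id = c("c1", "c2"))
  pot <- regulatory_potential(adjusted, clusters = clusters)
  expect_equal(pot$potential[pot$cluster_id == "c2"], 0)
})

test_that("the elbow rule recovers a planted two-population split exactly", {
  set.seed(42)
  pots <- tibble::tibble(cluster_id = paste0("c", 1:500),
                         potential = c(rep(10, 20), rnorm(480)))
  hubs <- call_hubs(pots)
  expect_equal(sum(hubs$is_hub), 20)
  expect_setequal(hubs$cluster_id[hubs$is_hub], paste0("c", 1:20))
  expect_equal(attr(hubs, "elbow_threshold"), 10)
  expect_false(attr(hubs, "degenerate"))
})

test_that("a monotone ramp is degenerate with at most one hub", {
  pots <- tibble::tibble(cluster_id = paste0("c", 1:100),
                         potential = seq(100, 1, length.out = 100))
  hubs <- call_hubs(pots)
  expect_true(attr(hubs, "degenerate"))
  expect_lte(sum(hubs$is_hub), 1)
})

test_that("all-equal potentials yield no hubs with a warning", {
  pots <- tibble::tibble(cluster_id = paste0("c", 1:50), potential = rep(1, 50))
  expect_warning(hubs <- call_hubs(pots), "equal")
  expect_equal(sum(hubs$is_hub), 0)
})

test_that("adding a constant shifts the threshold but not the hub set", {
  set.seed(9)
  pots <- tibble::tibble(cluster_id = paste0("c", 1:300),
                         potential = c(rep(8, 15), rnorm(285)))
  h1 <- call_hubs(pots)
  h2 <- call_hubs(dplyr::mutate(pots, potential = potential + 5))
  expect_equal(attr(h2, "elbow_threshold"), attr(h1, "elbow_threshold") + 5)
  expect_equal(h2$is_hub, h1$is_hub)
})

test_that("raising a hub's potential never evicts it from the hub set", {
  set.seed(3)
  pots <- tibble::tibble(cluster_id = paste0("c", 1:200),
                         potential = c(rep(6, 10), rnorm(190)))
  base <- call_hubs(pots)
  hub_ids <- base$cluster_id[base$is_hub]
  for (boost in c(1, 5, 50)) {
    up <- pots
    up$potential[up$cluster_id == hub_ids[1]] <-
      up$potential[up$cluster_id == hub_ids[1]] + boost
    again <- call_hubs(up)
    expect_true(again$is_hub[again$cluster_id == hub_ids[1]],
                label = paste("boost", boost))
  }
})
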