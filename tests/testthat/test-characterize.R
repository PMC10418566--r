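test_that("distance ranks count outward from the gene body per island class", {
  net <- make_net(
    edges = tibble::tibble(gene_id = "g1",
                           cluster_id = c("c1", "c2", "c3", "c4"),
                           d = c(-5e3, -4e4, 2e4, -1e3),
                           in_gene_body = c(FALSE, FALSE, FALSE, TRUE)),
    k = tibble::tibble(gene_id = "g1", k = 4L)
  )
  clusters <- tibble::tibble(cluster_id = paste0("c", 1:4),
                             in_island = c(TRUE, TRUE, FALSE, TRUE))
  cons <- tibble::tibble(gene_id = "g1", cluster_id = "c1", coefficient = -0.5)
  prof <- distance_rank_profile(net, cons, clusters)
  up <- prof[prof$region == "upstream", ]
  expect_equal(up$rank[order(up$mean_abs_distance)], c(-1L, -2L))
  expect_equal(prof$rank[prof$region == "downstream"], 1L)
  expect_equal(prof$region[is.na(prof$rank)], "gene_body")
  # candidate counts conserved over outside-body edges
  expect_equal(sum(prof$n_candidate[prof$region != "gene_body"]), 3)
})

test_that("planted negative effects at the first upstream island show up in the profile", {
  set.seed(8)
  n_genes <- 30
  edges <- purrr::map(seq_len(n_genes), function(i) {
    tibble::tibble(gene_id = sprintf("g%02d", i),
                   cluster_id = sprintf("g%02d_c%d", i, 1:4),
                   d = c(-8e3, -9e4, 5e4, 3e5),
                   in_gene_body = FALSE)
  }) |> purrr::list_rbind()
  net <- make_net(edges, dplyr::count(edges, gene_id, name = "k"))
  clusters <- tibble::tibble(cluster_id = edges$cluster_id, in_island = TRUE)
  # only the nearest upstream cluster of each gene carries a negative effect
  cons <- edges |>
    dplyr::filter(d == -8e3) |>
    dplyr::transmute(gene_id, cluster_id, coefficient = -1)
  prof <- distance_rank_profile(net, cons, clusters)
  m1 <- prof$mean_coefficient[prof$rank %in% -1]
  expect_lt(m1, 0)
  expect_equal(prof$mean_coefficient[!prof$rank %in% -1 & prof$region != "gene_body"],
               rep(0, 3))
  # probability equals the brute-force count ratio
  expect_equal(prof$association_probability[prof$rank %in% -1], 1)
  expect_equal(prof$n_retained[prof$rank %in% -1], n_genes)
})

state_fixture <- function(shift = 0, n = 60, seed = 1) {
  set.seed(seed)
  states <- rep(c("Low Signal", "Promoter", "Enhancer"), each = n / 3)
  pot <- rnorm(n, 0, 1) + shift * (states == "Promoter")
  list(potentials = tibble::tibble(cluster_id = paste0("c", 1:n), potential = pot),
       labels = tibble::tibble(cluster_id = paste0("c", 1:n), state = states))
}

test_that("state enrichment is zero when everything sits in the reference", {
  f <- state_fixture()
  f$labels$state <- "Low Signal"
  out <- state_enrichment(f$potentials, f$labels)
  expect_equal(nrow(out), 0)
})

test_that("state enrichment recovers a planted shift and the closed form", {
  f <- state_fixture(shift = 2)
  out <- state_enrichment(f$potentials, f$labels)
  prom <- out[out$term == "Promoter", ]
  expect_lt(abs(prom$effect - 2), 2 * prom$stderr)
  # balanced one-way design: effects equal group means minus reference mean
  df <- dplyr::inner_join(f$potentials, f$labels, by = "cluster_id")
  gm <- tapply(df$potential, df$state, mean)
  expect_equal(unname(prom$effect), unname(gm["Promoter"] - gm["Low Signal"]),
               tolerance = 1e-10)
})

test_that("a missing reference state is an error", {
  f <- state_fixture()
  expect_error(state_enrichment(f$potentials, f$labels, reference_label = "Insulator"),
               "absent")
})

test_that("cluster state labels take the most-overlapped state", {
  clusters <- tibble::tibble(cluster_id = c("a", "b"), chrom = "chr1",
                             start = c(100, 1000), end = c(300, 1100),
                             representative_pos = c(200, 1050))
  states <- tibble::tibble(chrom = "chr1",
                           start = c(0, 250, 2000), end = c(250, 400, 3000),
                           label = c("Promoter", "Enhancer", "Low Signal"))
  lab <- label_clusters_by_state(clusters, states)
  expect_equal(lab$state[lab$cluster_id == "a"], "Promoter")  # 150 bp vs 50 bp
  expect_equal(lab$state[lab$cluster_id == "b"], "Low Signal")  # no overlap
})

test_that("TF enrichment reduces to marginal differences for orthogonal factors", {
  set.seed(2)
  n <- 80
  B <- cbind(F1 = rep(c(1, 0), each = n / 2),
             F2 = c(rep(0, n / 2), rep(1, n / 4), rep(0, n / 4)))
  pot <- rnorm(n) + 1.5 * B[, "F1"]
  rownames(B) <- paste0("c", 1:n)
  pots <- tibble::tibble(cluster_id = rownames(B), potential = pot)
  out <- tfbs_enrichment(pots, B)
  # with disjoint factors the joint fit equals per-factor mean contrasts
  base <- mean(pot[B[, "F1"] == 0 & B[, "F2"] == 0])
  expect_equal(unname(out$effect[out$term == "F1"]),
               mean(pot[B[, "F1"] == 1]) - base, tolerance = 1e-10)
  expect_equal(unname(out$effect[out$term == "F2"]),
               mean(pot[B[, "F2"] == 1]) - base, tolerance = 1e-10)
})

test_that("collinear factors are dropped deterministically, unbound ones warned", {
  set.seed(3)
  n <- 40
  f <- rbinom(n, 1, 0.4)
  B <- cbind(TF_b = f, TF_a = f, TF_zero = 0)
  rownames(B) <- paste0("c", 1:n)
  pots <- tibble::tibble(cluster_id = rownames(B), potential = rnorm(n) + f)
  warns <- character()
  out <- withCallingHandlers(
    tfbs_enrichment(pots, B),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  expect_true(any(grepl("TF_zero", warns)))
  # lexicographically first (TF_a) is kept, duplicate TF_b dropped
  expect_true("TF_a" %in% out$term)
  expect_false("TF_b" %in% out$term)
})

test_that("the joint TF model is less confounded than marginal contrasts", {
  set.seed(4)
  n <- 400
  A <- rbinom(n, 1, 0.3)
  B <- ifelse(A == 1, rbinom(n, 1, 0.8), rbinom(n, 1, 0.1))  # co-binds with A
  pot <- 2 * A + rnorm(n)
  bind <- cbind(A = A, B = B)
  rownames(bind) <- paste0("c", 1:n)
  pots <- tibble::tibble(cluster_id = rownames(bind), potential = pot)
  out <- tfbs_enrichment(pots, bind)
  joint_bias_B <- abs(out$effect[out$term == "B"])
  marginal_bias_B <- abs(mean(pot[B == 1]) - mean(pot[B == 0]))
  expect_lt(joint_bias_B, marginal_bias_B)
  expect_lt(abs(out$effect[out$term == "A"] - 2), 4 * out$stderr[out$term == "A"])
})

test_that("bin potentials equal a brute-force sum of member clusters", {
  fx <- get_smoke()
  set.seed(6)
  pots <- tibble::tibble(cluster_id = fx$clusters$cluster_id,
                         potential = rnorm(nrow(fx$clusters)))
  bins <- bin_potentials(pots, fx$clusters, 2500)
  brute <- tapply(pots$potential,
                  floor(fx$clusters$representative_pos / 2500) * 2500, sum)
  expect_equal(bins$potential[match(as.numeric(names(brute)), bins$bin_start)],
               as.numeric(brute), tolerance = 1e-12)
})

test_that("quartile enrichment recovers a planted loop/potential coupling", {
  fx <- get_smoke()
  set.seed(12)
  pots <- tibble::tibble(cluster_id = fx$clusters$cluster_id,
                         potential = rnorm(nrow(fx$clusters)))
  # put loops on the top-potential clusters so quartile effects increase
  top <- pots$cluster_id[order(-pots$potential)][1:30]
  anchors <- fx$clusters[match(top, fx$clusters$cluster_id), ]
  loops <- tibble::tibble(
    chrom1 = anchors$chrom,
    start1 = floor(anchors$representative_pos / 2500) * 2500,
    end1 = start1 + 2500,
    chrom2 = anchors$chrom, start2 = 0, end2 = 2500,
    source = "sim", is_cis = TRUE
  )
  loops <- dplyr::bind_rows(loops, loops[1:10, ], loops[1:5, ])  # graded counts
  out <- suppressWarnings(
    loop_quartile_enrichment(pots, loops, fx$clusters, bin_size = 2500)
  )
  expect_gt(nrow(out), 0)
  expect_true(all(out$effect > 0))
})

test_that("no loops at all yields zero contrasts with a warning", {
  fx <- get_smoke()
  pots <- tibble::tibble(cluster_id = fx$clusters$cluster_id, potential = 1)
  loops <- tibble::tibble(chrom1 = character(), start1 = numeric(),
                          end1 = numeric(), chrom2 = character(),
                          start2 = numeric(), end2 = numeric(),
                          source = character(), is_cis = logical())
  expect_warning(out <- loop_quartile_enrichment(pots, loops, fx$clusters),
                 "no loops")
  expect_equal(nrow(out), 0)
})

surv_fixture <- function(n = 400, effect = 1, seed = 1) {
  set.seed(seed)
  betas <- matrix(runif(3 * n), 3, n,
                  dimnames = list(c("e1", "e2", "e3"), paste0("s", 1:n)))
  samples <- tibble::tibble(sample_id = paste0("s", 1:n),
                            context = rep(c("A", "B"), each = n / 2),
                            sample_type = "tumor",
                            os_event = NA_real_, os_time = NA_real_)
  eff <- tibble::tibble(cluster_id = "e1", loghaz = effect)
  samples <- simulate_survival(betas, eff, samples, censoring_rate = 0.2,
                               seed = seed)
  list(betas = betas, samples = samples)
}

test_that("the stratified varying-slope hazard model recovers a planted effect", {
  f <- surv_fixture(effect = 1, seed = 2)
  out <- survival_association(f$betas, f$samples, hubs = character(),
                              variance_quantile = 0, seed = 1)
  pooled <- out[out$term == "pooled" & out$cluster_id == "e1", ]
  expect_lt(abs(pooled$effect - 1), 2.5 * pooled$stderr)
  # per-context deviation terms exist
  expect_true(any(out$term != "pooled"))
})

test_that("an all-censored element reports missing estimates, not a crash", {
  f <- surv_fixture()
  f$samples$os_event <- 0
  out <- survival_association(f$betas, f$samples, variance_quantile = 0, seed = 1)
  expect_true(all(is.na(out$effect)))
})

test_that("the variance filter excludes the least variable elements", {
  set.seed(5)
  betas <- rbind(flat = rep(0.5, 200) + rnorm(200, 0, 0.001),
                 var1 = runif(200), var2 = runif(200), var3 = runif(200))
  colnames(betas) <- paste0("s", 1:200)
  samples <- tibble::tibble(sample_id = colnames(betas), context = "A",
                            sample_type = "tumor", os_event = NA_real_,
                            os_time = NA_real_)
  samples <- simulate_survival(betas, tibble::tibble(cluster_id = character(),
                                                     loghaz = numeric()),
                               samples, seed = 1)
  out <- survival_association(betas, samples, variance_quantile = 0.25, seed = 1)
  expect_false("flat" %in% out$cluster_id)
})
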