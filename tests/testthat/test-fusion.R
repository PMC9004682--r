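test_that("smoothing operator is row-stochastic with a dominant diagonal", {
  withr::with_seed(1, {
    coords <- matrix(rnorm(200), 100, 2)
    op <- build_smoothing_operator(coords, k = 10, ka = 3, p = 0.7)
    expect_lt(max(abs(Matrix::rowSums(op$weights) - 1)), 1e-9)
    expect_true(all(Matrix::diag(op$weights) >= 0.7 - 1e-12))
    # p = 1 collapses to the identity
    op1 <- build_smoothing_operator(coords, k = 10, ka = 3, p = 1)
    expect_lt(max(abs(op1$weights - Matrix::Diagonal(100))), 1e-12)
  })
})

test_that("smoothing preserves constants and bounds indicators", {
  withr::with_seed(2, {
    coords <- matrix(rnorm(160), 80, 2)
    op <- build_smoothing_operator(coords, k = 8, ka = 2, p = 0.5)
    const <- matrix(3, 80, 2)
    expect_equal(smooth_features(const, op), const, ignore_attr = TRUE)
    indicator <- matrix(rep(c(1, 0), each = 40), 80, 1)
    sm <- smooth_features(indicator, op)
    expect_true(all(sm >= 0 & sm <= 1))
    expect_error(smooth_features(matrix(0, 10, 2), op),
                 class = "methylfusion_bad_argument")
  })
})

test_that("duplicate points trigger the bandwidth fallback with a warning", {
  coords <- rbind(matrix(0, 5, 2), matrix(rnorm(40), 20, 2))
  expect_warning(build_smoothing_operator(coords, k = 6, ka = 3, p = 0.5),
                 "duplicate")
})

test_that("restricted k-partners matches the reference implementation", {
  withr::with_seed(20, {
    for (case in 1:4) {
      ns <- sample(10:40, 1); nt <- sample(10:40, 1)
      k <- sample(2:4, 1); z <- sample(c(1, 2, 3), 1)
      src <- matrix(rnorm(ns * 5), ns, 5)
      tgt <- matrix(rnorm(nt * 5), nt, 5)
      g <- restricted_k_partners(src, tgt, k = k, z = z, seed = case)
      ref <- rkp_reference(src, tgt, k = k, z = z, seed = case)
      expect_identical(unname(g$partners), ref)
    }
    # spearman metric against the same oracle
    src <- matrix(rnorm(15 * 20), 15, 20)
    tgt <- matrix(rnorm(12 * 20), 12, 20)
    g <- restricted_k_partners(src, tgt, k = 2, z = 2, seed = 5,
                               metric = "one_minus_spearman")
    ref <- rkp_reference(src, tgt, k = 2, z = 2, seed = 5,
                         metric = "one_minus_spearman")
    expect_identical(unname(g$partners), ref)
  })
})

test_that("restricted k-partners respects capacities and determinism", {
  withr::with_seed(21, {
    src <- matrix(rnorm(60), 30, 2)
    tgt <- matrix(rnorm(60), 30, 2)
    g <- restricted_k_partners(src, tgt, k = 2, z = 1, seed = 3)
    # z = 1: every target carries exactly k' or k' - 1 partners
    expect_true(all(g$target_counts %in% c(g$k_prime, g$k_prime - 1)))
    expect_true(all(g$target_counts <= g$k_prime))
    # k' formula
    g2 <- restricted_k_partners(matrix(rnorm(20), 10, 2),
                                matrix(rnorm(10), 5, 2), k = 3, z = 3,
                                seed = 1)
    expect_equal(g2$k_prime, ceiling(3 * 3 * 10 / 5))
    # identical coordinates: each source partners with itself first
    same <- matrix(seq_len(20), 20, 1)
    g3 <- restricted_k_partners(same, same, k = 1, z = 20, seed = 2)
    expect_equal(g3$partners[, 1], seq_len(20))
    # seed determinism
    expect_identical(restricted_k_partners(src, tgt, 3, 2, seed = 9),
                     restricted_k_partners(src, tgt, 3, 2, seed = 9))
    expect_error(restricted_k_partners(src, tgt, 2, z = 0.5),
                 class = "methylfusion_bad_argument")
  })
})

test_that("imputation averages partner feature vectors", {
  g <- structure(list(partners = matrix(c(1L, 2L), 1), k = 2),
                 class = "partner_graph")
  feats <- rbind(c(0, 2), c(2, 0))
  expect_equal(impute_cross_modality(g, feats), matrix(c(1, 1), 1))
  g1 <- structure(list(partners = matrix(2L, 1), k = 1),
                  class = "partner_graph")
  expect_equal(impute_cross_modality(g1, feats), matrix(c(2, 0), 1))
  g_bad <- structure(list(partners = matrix(5L, 1), k = 1),
                     class = "partner_graph")
  expect_error(impute_cross_modality(g_bad, feats),
               class = "methylfusion_bad_argument")
})

test_that("label transfer requires a majority and breaks ties fixedly", {
  g <- structure(list(partners = matrix(1:10, 1), k = 10),
                 class = "partner_graph")
  expect_equal(transfer_labels(g, rep("X", 10)), "X")
  expect_equal(transfer_labels(g, c(rep("A", 4), rep("B", 3), rep("C", 3))),
               "UNASSIGNED")
  # exact 5/5 tie with equal global support: lexicographic winner
  expect_equal(transfer_labels(g, rep(c("B", "A"), each = 5)), "A")
})

test_that("fusing coupled data co-clusters the two modalities", {
  sim <- generate_multimodal(synthetic_config(
    n_cells = 450, n_genes = 600, n_clusters = 3, coupled_fraction = 0.5,
    seed = 0
  ))
  truth <- sim$truth
  mchn <- raw_rates(sim$mc_counts) / truth$per_cell_global
  expr <- normalize_expression(sim$rna_counts)
  coupled <- colnames(expr)[truth$coupled_genes]
  fu <- fuse_datasets(mchn, expr, shared_genes = coupled, seed = 0)
  n <- nrow(mchn)
  ev <- evaluate_fusion(fu$coords, cbind(seq_len(n), n + seq_len(n)),
                        target_n_coclusters = 3, seed = 1)
  expect_gte(ev$cocluster_accuracy, 0.9)
  # joint clusters agree with the planted populations on the mC side
  expect_gte(adjusted_rand_index(ev$coclusters[seq_len(n)],
                                 truth$cluster_labels), 0.9)
})

test_that("a dataset fused with its mirrored copy aligns perfectly", {
  withr::with_seed(6, {
    expr <- matrix(rnorm(200 * 80, 5), 200, 80)
    expr[1:100, 1:40] <- expr[1:100, 1:40] + 3  # two populations
    colnames(expr) <- paste0("g", 1:80)
    mirrored <- max(expr) - expr  # fuse_datasets re-reverses this internally
    fu <- fuse_datasets(mirrored, expr, seed = 2)
    ev <- evaluate_fusion(fu$coords, cbind(1:200, 201:400),
                          target_n_coclusters = 2, seed = 3)
    expect_equal(ev$cocluster_accuracy, 1)
  })
})

test_that("fusion accuracy increases with the coupled gene fraction", {
  acc <- vapply(c(0.05, 0.3, 1), function(cf) {
    sim <- generate_multimodal(synthetic_config(
      n_cells = 300, n_genes = 400, n_clusters = 3, coupled_fraction = cf,
      seed = 42
    ))
    truth <- sim$truth
    mchn <- raw_rates(sim$mc_counts) / truth$per_cell_global
    expr <- normalize_expression(sim$rna_counts)
    fu <- fuse_datasets(mchn, expr, seed = 1)
    ev <- evaluate_fusion(fu$coords, cbind(1:300, 301:600),
                          target_n_coclusters = 3, seed = 1)
    ev$cocluster_accuracy
  }, numeric(1))
  expect_gt(cor(acc, c(0.05, 0.3, 1), method = "spearman"), 0)
  expect_gt(acc[3], acc[1])
})
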