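make_coembedding <- function(u, v = u) {
  structure(list(u = as.matrix(u), v = as.matrix(v),
                 singular_values = rep(1, ncol(as.matrix(u)))),
            class = "coembedding")
}

test_that("CCA co-embedding of identical matrices matches cells to themselves", {
  withr::with_seed(1, {
    x <- matrix(rnorm(50 * 30), 50, 30)
    ce <- cca_coembed(x, x, n_components = 5)
    expect_true(all(self_radii(ce) == 0))
  })
})

test_that("CCA handles rank deficiency and zero-variance columns", {
  withr::with_seed(2, {
    base <- matrix(rnorm(40 * 2), 40, 2)
    x <- base %*% matrix(rnorm(2 * 10), 2, 10)   # rank 2
    expect_warning(ce <- cca_coembed(x, x, n_components = 5), "Rank")
    expect_equal(ncol(ce$u), 2L)

    x2 <- cbind(x, 0)  # zero column dropped from both sides
    expect_warning(ce2 <- cca_coembed(x2, cbind(x, 1), n_components = 2),
                   NA)
    expect_equal(ncol(ce2$u), 2L)
  })
})

test_that("cross-modal partners sort by distance with index tie-breaks", {
  ce <- make_coembedding(matrix(c(0, 1, 3), 3, 1))
  partners <- cross_modal_partners(ce, k = 2)
  expect_equal(partners[2, ], c(2, 1))   # cell at 1: itself, then cell at 0
  full <- cross_modal_partners(ce, k = 3)
  expect_equal(dim(full), c(3L, 3L))
  expect_error(cross_modal_partners(ce, k = 4),
               class = "methylfusion_bad_argument")
})

test_that("partners and self-radii agree with brute force on small instances", {
  withr::with_seed(3, {
    for (n in c(40, 200)) {
      u <- matrix(rnorm(n * 4), n, 4)
      v <- u + matrix(rnorm(n * 4, sd = 0.5), n, 4)
      ce <- make_coembedding(u, v)
      d <- as.matrix(dist(rbind(u, v)))[1:n, n + 1:n]
      # k-partner lists
      k <- 7
      expected <- unname(t(apply(d, 1, function(r) {
        order(r, seq_along(r))[1:k]
      })))
      expect_equal(unname(cross_modal_partners(ce, k)), expected)
      # self-radii
      expected_r <- vapply(1:n, function(i) sum(d[i, -i] < d[i, i]),
                           integer(1))
      expect_identical(self_radii(ce), unname(expected_r))
    }
  })
})

test_that("over-splitting score hits its formula bounds", {
  fx <- paired_two_cluster()
  so <- over_splitting_score(fx$ce, fx$labels)
  expect_true(all(so$s_over < 0.05))

  # all partners outside the cluster: score 1 by construction
  u <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  v <- rbind(matrix(10, 5, 2), matrix(0, 5, 2))  # modalities swapped
  so2 <- over_splitting_score(make_coembedding(u, v),
                              rep(c("a", "b"), each = 5))
  expect_true(all(so2$s_over == 1))
})

test_that("randomly split homogeneous clusters score S_over near one half", {
  fx <- paired_two_cluster()
  s_over_halves <- vapply(1:3, function(s) {
    split <- perturb_labels(fx$labels, "split", seed = s, clusters = "C1")
    so <- over_splitting_score(fx$ce, split)
    mean(so$s_over[so$cluster %in% c("C1.a", "C1.b")])
  }, numeric(1))
  expect_lt(abs(mean(s_over_halves) - 0.5), 0.05)
})

test_that("under-splitting score is the CDF slope of normalized radii", {
  labels <- rep("A", 100)
  # uniform normalized radii -> score 1 (up to grid discreteness)
  expect_equal(under_splitting_score(0:99, labels)$s_under, 1,
               tolerance = 0.05)
  # all radii zero -> 1 / quantile
  expect_equal(under_splitting_score(rep(0, 100), labels)$s_under, 4)
  # all radii beyond the quantile -> 0
  expect_equal(under_splitting_score(rep(60, 100), labels)$s_under, 0)
})

test_that("shuffled homogeneous clusters have uniform self-radii", {
  fx <- paired_two_cluster()
  ideal <- make_ideal_reference(fx$mchn, fx$expr, fx$labels, seed = 5)
  ce <- cca_coembed(ideal$x, ideal$y, n_components = 20, reverse_x = TRUE)
  radii <- self_radii(ce)
  in_c1 <- fx$labels == "C1"
  rho <- radii[in_c1] / sum(in_c1)
  ks <- suppressWarnings(ks.test(rho, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("merging separated clusters pushes S_under above one", {
  fx <- paired_two_cluster()
  merged <- perturb_labels(fx$labels, "merge", seed = 2)
  su <- under_splitting_score(self_radii(fx$ce), merged)
  expect_gt(su$s_under[su$cluster == "C1+C2"], 1)
})

test_that("ideal-reference shuffling preserves marginals, destroys coupling", {
  fx <- paired_two_cluster()
  ideal <- make_ideal_reference(fx$mchn, fx$expr, fx$labels, seed = 9)
  for (cl in c("C1", "C2")) {
    idx <- fx$labels == cl
    expect_equal(colMeans(ideal$x[idx, ]), colMeans(fx$mchn[idx, ]),
                 ignore_attr = TRUE)
    expect_equal(colMeans(ideal$y[idx, ]), colMeans(fx$expr[idx, ]),
                 ignore_attr = TRUE)
  }
  cell_cor <- function(x, y) {
    mean(abs(vapply(seq_len(nrow(x)), function(i) {
      suppressWarnings(cor(x[i, ], y[i, ], method = "spearman"))
    }, numeric(1))), na.rm = TRUE)
  }
  expect_lt(cell_cor(max(ideal$x) - ideal$x, ideal$y),
            cell_cor(max(fx$mchn) - fx$mchn, fx$expr))
  expect_identical(make_ideal_reference(fx$mchn, fx$expr, fx$labels, 9),
                   ideal)
})

test_that("information criteria match their closed form", {
  ic <- information_criteria(0.5, n = 100, d = 5, sigma2 = 1)
  expect_equal(ic[["aic"]], 0.6)
  expect_equal(ic[["bic"]], 0.5 + log(100) * 5 / 100, tolerance = 1e-10)
  # penalties vanish as N grows
  big <- information_criteria(0.5, n = 1e7, d = 5, sigma2 = 1)
  expect_equal(unname(big), c(0.5, 0.5), tolerance = 1e-4)
  expect_error(information_criteria(0.5, 10, 2, -1),
               class = "methylfusion_bad_argument")
})

test_that("BIC selects no more clusters than AIC on a convex error curve", {
  d <- 1:20
  for (n in c(50, 200, 1000)) {
    train_mse <- 2 / sqrt(d)  # convex, decreasing fit term
    ic <- vapply(d, function(di) {
      information_criteria(train_mse[di], n = n, d = di, sigma2 = 1)
    }, numeric(2))
    expect_lte(d[which.min(ic[2, ])], d[which.min(ic[1, ])])
  }
})

test_that("cross-validation curves locate the planted cluster number", {
  sim <- generate_multimodal(synthetic_config(
    n_cells = 400, n_genes = 500, n_clusters = 4, coupled_fraction = 0.3,
    seed = 6
  ))
  truth <- sim$truth
  mchn <- raw_rates(sim$mc_counts) / truth$per_cell_global
  expr <- normalize_expression(sim$rna_counts)
  cv <- cv_error_curve(mchn, expr, resolutions = c(0.05, 0.2, 0.5, 1, 2, 4),
                       n_folds = 3, n_seeds = 2, seed = 5)
  agg <- dplyr::summarise(dplyr::group_by(cv, n_clusters),
                          train = mean(train_mse), test = mean(test_mse),
                          aic = mean(aic), .groups = "drop")
  agg <- dplyr::arrange(agg, n_clusters)
  # training error decreases with granularity; test error does not
  expect_true(all(diff(agg$train) <= 0.01))
  expect_true(all(agg$test >= agg$train))
  best <- agg$n_clusters[which.min(agg$test)]
  expect_lte(abs(best - 4), 1)
  # AIC tracks the out-of-sample error across granularities
  expect_gt(cor(agg$aic, agg$test), 0.8)
})

test_that("a constant evaluation modality yields flat curves", {
  withr::with_seed(7, {
    cl_mat <- matrix(rnorm(120 * 50), 120, 50)
    flat <- matrix(5, 120, 20)
    cv <- cv_error_curve(cl_mat, flat, resolutions = c(0.5, 2),
                         n_folds = 2, n_seeds = 1, seed = 1)
    expect_true(all(cv$train_mse == 0))
    expect_true(all(cv$test_mse == 0))
  })
})

test_that("fusion metrics behave at their extremes", {
  withr::with_seed(8, {
    coords <- matrix(rnorm(100 * 5), 100, 5)
    joint <- rbind(coords, coords)  # perfect fusion: identical profiles
    pairs <- cbind(1:100, 101:200)
    ev <- evaluate_fusion(joint, pairs, target_n_coclusters = 1, seed = 1)
    expect_equal(ev$mis_fusion_ratio, 0)
    expect_true(all(ev$per_cell$rank == 1))
    expect_equal(ev$cocluster_accuracy, 1)

    # unrelated profiles: ranks ~ uniform, mis-fusion ratio near 1 - 0.3
    random <- matrix(rnorm(400 * 5), 400, 5)
    ev0 <- evaluate_fusion(random, cbind(1:200, 201:400))
    expect_lt(abs(ev0$mis_fusion_ratio - 0.7), 0.08)
    ev1 <- evaluate_fusion(random, cbind(1:200, 201:400),
                           misfusion_threshold = 1)
    expect_equal(ev1$mis_fusion_ratio, 0)
  })
})

test_that("overlap scores sum minimum co-cluster proportions", {
  cells <- paste0("s", 1:120)
  lab <- setNames(rep(c("a", "b", "c", "d"), each = 30), cells)
  identical_score <- overlap_score(lab, lab, lab)
  expect_equal(unname(diag(identical_score)), rep(1, 4))
  expect_equal(sum(identical_score) - sum(diag(identical_score)), 0)

  # clusters that never share a co-cluster score 0
  co <- setNames(rep(c("g1", "g2"), each = 60), cells)
  sc <- overlap_score(setNames(rep("a", 60), cells[1:60]),
                      setNames(rep("z", 60), cells[61:120]), co)
  expect_equal(sc["a", "z"], 0)

  # a fully inside g, b half inside: min(1, 0.5) = 0.5
  a <- setNames(rep("a", 30), cells[1:30])
  b <- setNames(rep("b", 60), cells[1:60])
  co2 <- setNames(c(rep("g", 30), rep("h", 90)), cells)
  expect_equal(overlap_score(a, b, co2)["a", "b"], 0.5)
})
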