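blob_embedding <- function(n_per = 60, k_blobs = 2, sep = 8, seed = 1) {
  withr::with_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(k_blobs), function(b) {
      cbind(rnorm(n_per, b * sep), rnorm(n_per), rnorm(n_per))
    }))
    list(coords = coords, labels = rep(paste0("B", seq_len(k_blobs)),
                                       each = n_per))
  })
}

test_that("Leiden ensembles are seed-deterministic and stable on clean data", {
  blobs <- blob_embedding()
  e1 <- run_leiden_ensemble(blobs$coords, k_neighbors = 15, resolution = 0.5,
                            n_runs = 10, seed = 4)
  e2 <- run_leiden_ensemble(blobs$coords, k_neighbors = 15, resolution = 0.5,
                            n_runs = 10, seed = 4)
  expect_identical(e1, e2)
  # every run finds the same 2-blob partition up to label permutation
  d <- consensus_distance(e1)
  same <- outer(blobs$labels, blobs$labels, "==")
  expect_true(all(d[same] == 0))
  expect_true(all(d[!same] == 1))

  single <- run_leiden_ensemble(blobs$coords, k_neighbors = 15,
                                resolution = 0.5, n_runs = 1, seed = 4)
  expect_equal(ncol(single$assignments), 1L)
  expect_identical(single$assignments[, 1], e1$assignments[, 1])
})

test_that("consensus distance counts disagreeing runs, permutation-safely", {
  a <- cbind(rep(1:2, each = 2), rep(2:1, each = 2), c(1, 1, 1, 2),
             c(1, 2, 2, 2))
  d <- consensus_distance(a)
  expect_equal(d[1, 2], 0.25)  # cells 1,2 co-labeled in 3 of 4 runs
  expect_equal(max(d), 1)
  expect_true(all(diag(d) == 0))
  # relabeling runs leaves the distance unchanged
  a_perm <- apply(a, 2, function(col) match(col, unique(col)) + 10)
  expect_equal(consensus_distance(a_perm), d, ignore_attr = TRUE)
})

test_that("density consensus recovers unanimous partitions and extremes", {
  blobs <- blob_embedding()
  ens <- run_leiden_ensemble(blobs$coords, k_neighbors = 15, resolution = 0.5,
                             n_runs = 20, seed = 4)
  versions <- consensus_partition(ens, epsilon_grid = c(0.1, 0.5, 1))
  n_cl <- vapply(versions, `[[`, integer(1), "n_clusters")
  expect_true(!is.unsorted(n_cl))
  exact <- versions[[which(n_cl == 2)[1]]]
  expect_equal(exact$outlier_fraction, 0)
  expect_equal(adjusted_rand_index(exact$labels, blobs$labels), 1)
  # epsilon = 1: all pairwise distances are <= 1, one cluster, no outliers
  merged <- versions[[1]]  # versions are sorted by increasing n_clusters
  expect_equal(merged$n_clusters, 1L)
  expect_equal(merged$outlier_fraction, 0)
  expect_error(consensus_partition(ens, epsilon_grid = numeric(0)),
               class = "methylfusion_bad_argument")
})

test_that("supervised evaluation scores separable and random labels", {
  blobs <- blob_embedding(n_per = 80, k_blobs = 3, seed = 2)
  fit <- evaluate_partition(blobs$coords, blobs$labels, n_folds = 3,
                            seed = 1, num_trees = 100)
  expect_gt(fit$score, 0.99)

  perm <- withr::with_seed(5, sample(blobs$labels))
  fit0 <- evaluate_partition(blobs$coords, perm, n_folds = 3, seed = 1,
                             num_trees = 100)
  expect_lt(abs(fit0$score - 1 / 3), 0.15)

  expect_error(evaluate_partition(blobs$coords, rep("A", 240)),
               class = "methylfusion_single_cluster")
})

test_that("outlier rescue assigns confident cells and keeps uncertain ones", {
  blobs <- blob_embedding(n_per = 80, k_blobs = 3, seed = 2)
  labels <- blobs$labels
  labels[c(1, 100)] <- "OUTLIER"
  fit <- evaluate_partition(blobs$coords, labels, n_folds = 3, seed = 1,
                            num_trees = 100)
  rescued <- rescue_outliers(fit, blobs$coords, labels)
  expect_equal(rescued[1], "B1")
  expect_equal(rescued[100], "B2")
  expect_identical(rescue_outliers(fit, blobs$coords, blobs$labels),
                   blobs$labels)
})

test_that("resolution selection takes the maximum qualifying candidate", {
  version <- function(n_clusters, outlier_fraction, n = 300) {
    labels <- rep(paste0("c", seq_len(n_clusters)), length.out = n)
    labels[seq_len(round(outlier_fraction * n))] <- "OUTLIER"
    structure(list(labels = labels, epsilon = 0.5, n_clusters = n_clusters,
                   outlier_fraction = outlier_fraction),
              class = "consensus_version")
  }
  cands <- list(
    list(resolution = 0.5, version = version(4, 0.01), score = 0.99),
    list(resolution = 1.0, version = version(6, 0.02), score = 0.97),
    list(resolution = 2.0, version = version(9, 0.10), score = 0.97),
    list(resolution = 4.0, version = version(12, 0.02), score = 0.90)
  )
  expect_equal(select_resolution(cands), 1.0)
  expect_equal(select_resolution(cands[1]), 0.5)
  low <- lapply(cands, function(x) { x$score <- 0.9; x })
  expect_error(select_resolution(low),
               class = "methylfusion_no_qualifying_resolution")
})

test_that("marker detection flags exclusive genes and ignores flat genes", {
  withr::with_seed(8, {
    n <- 90
    labels <- rep(c("A", "B", "C"), each = 30)
    flat <- rnorm(n, 5)
    exclusive <- ifelse(labels == "A", rnorm(n, 50), 0)
    mat <- cbind(excl = exclusive, flat = flat)
    mk <- find_markers(mat, labels, "rna")
    expect_true(mk$is_marker[mk$cluster == "A" & mk$gene == "excl"])
    expect_equal(mk$auroc[mk$cluster == "A" & mk$gene == "excl"], 1)
    expect_false(any(mk$is_marker[mk$gene == "flat"]))
    # a gene cannot be a marker of both a cluster and its complement
    expect_false(any(mk$is_marker[mk$cluster != "A" & mk$gene == "excl"]))
  })
})

test_that("hypomethylated genes become methylation markers", {
  withr::with_seed(9, {
    labels <- rep(c("A", "B"), each = 40)
    hypo <- ifelse(labels == "A", rnorm(80, 0.4, 0.05), rnorm(80, 1, 0.05))
    other <- rnorm(80, 1, 0.05)
    mk <- find_markers(cbind(hypo = hypo, other = other), labels, "mch")
    expect_true(mk$is_marker[mk$cluster == "A" & mk$gene == "hypo"])
    expect_lt(mk$effect[mk$cluster == "A" & mk$gene == "hypo"], -0.3)
    expect_false(any(mk$is_marker[mk$gene == "other"]))
  })
})

test_that("artificially split clusters re-merge for lack of markers", {
  fx <- paired_two_cluster()
  nr <- normalize_rates(fx$sim$mc_counts)
  pcs <- embed_methylome(nr, n_pcs = 10)
  split <- perturb_labels(fx$labels, "split", seed = 1, clusters = "C1")
  merged <- merge_weak_clusters(split, nr, pcs, modality = "mch")
  expect_equal(length(unique(merged)), 2L)
  expect_equal(adjusted_rand_index(merged, fx$labels), 1)
  # a healthy partition is left untouched
  expect_identical(merge_weak_clusters(fx$labels, nr, pcs, modality = "mch"),
                   fx$labels)
})

test_that("the full consensus pipeline recovers five planted clusters", {
  fx <- five_cluster()
  ens <- run_leiden_ensemble(fx$pcs, k_neighbors = 25, resolution = 1,
                             n_runs = 25, seed = 10)
  versions <- consensus_partition(ens, epsilon_grid = seq(0.05, 1, by = 0.05))
  v <- NULL
  for (vv in versions) {
    if (vv$n_clusters == 5 && vv$outlier_fraction < 0.05) { v <- vv; break }
  }
  expect_false(is.null(v))
  fit <- evaluate_partition(fx$pcs, v$labels, n_folds = 5, seed = 3,
                            num_trees = 100)
  expect_gt(fit$score, 0.95)
  final <- rescue_outliers(fit, fx$pcs, v$labels)
  keep <- final != "OUTLIER"
  expect_gte(adjusted_rand_index(final[keep], fx$labels[keep]), 0.9)
})
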