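#' Build a symmetrized unweighted KNN graph
#'
#' @param coords Cell-by-component coordinate matrix.
#' @param k Number of neighbors.
#' @return An [igraph::graph] with one vertex per row of `coords`.
#' @export
knn_graph <- function(coords, k = 25) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) mf_abort("`k` must be below the number of cells.",
                       "bad_argument")
  nn <- RANN::nn2(coords, k = k + 1)$nn.idx[, -1, drop = FALSE]
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering on a KNN graph of an embedding
#'
#' @param coords Cell-by-component matrix.
#' @param resolution Leiden resolution (modularity objective).
#' @param k Neighbors for the KNN graph.
#' @param seed Integer seed for the random start.
#' @param graph Optional prebuilt [knn_graph()] (overrides `coords`/`k`).
#' @return Integer cluster labels.
#' @export
leiden_cluster <- function(coords = NULL, resolution = 1, k = 25, seed = 1L,
                           graph = NULL) {
  if (is.null(graph)) graph <- knn_graph(coords, k)
  with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = 2
    ))
  })
}

#' Run a Leiden ensemble with different random starts
#'
#' Builds the KNN graph once and repeats Leiden clustering `n_runs` times
#' with seeds `seed .. seed + n_runs - 1`, collecting every partition as a
#' column of an assignment matrix. The run-to-run variability of these
#' partitions is what the density consensus summarizes.
#'
#' @param embedding Cell-by-component coordinates (e.g. concatenated
#'   per-modality PCs).
#' @param k_neighbors KNN graph size (default 25).
#' @param resolution Leiden resolution.
#' @param n_runs Ensemble size (default 200).
#' @param seed Base seed.
#'
#' @return A list of class `clustering_ensemble` with `assignments`
#'   (cell-by-run integer matrix), `resolution`, `seeds`.
#' @export
run_leiden_ensemble <- function(embedding, k_neighbors = 25, resolution = 1,
                                n_runs = 200, seed = 1L) {
  assert_count(n_runs, "n_runs")
  g <- knn_graph(embedding, k_neighbors)
  seeds <- seq.int(seed, length.out = n_runs)
  assignments <- vapply(
    seeds,
    function(s) as.integer(leiden_cluster(graph = g, resolution = resolution,
                                          seed = s)),
    integer(nrow(embedding))
  )
  rownames(assignments) <- rownames(embedding)
  structure(list(assignments = assignments, resolution = resolution,
                 seeds = seeds),
            class = "clustering_ensemble")
}

#' Pairwise Hamming distance between cells over ensemble runs
#'
#' Distance between two cells is the fraction of runs in which they receive
#' different labels; invariant under per-run label permutation and a
#' pseudometric in \[0,1\].
#'
#' @param ensemble A `clustering_ensemble` (or its assignment matrix).
#' @return Dense symmetric cell-by-cell matrix.
#' @export
consensus_distance <- function(ensemble) {
  a <- if (inherits(ensemble, "clustering_ensemble")) ensemble$assignments
       else as.matrix(ensemble)
  n <- nrow(a)
  d <- matrix(0, n, n)
  for (r in seq_len(ncol(a))) {
    d <- d + outer(a[, r], a[, r], "!=")
  }
  d / ncol(a)
}

# textbook DBSCAN on a precomputed distance matrix; min_pts counts the
# point itself (sklearn convention). Returns integer labels, 0 = noise.
dbscan_precomputed <- function(d, eps, min_pts) {
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Density consensus over a Leiden ensemble
#'
#' Runs outlier-aware density clustering (DBSCAN) on the ensemble Hamming
#' distance at each epsilon in a grid, producing one candidate consensus
#' version per epsilon. Cells not attached to any dense core are labelled
#' `"OUTLIER"`.
#'
#' @param ensemble A `clustering_ensemble`.
#' @param epsilon_grid Distance thresholds to traverse (default 50 values in
#'   (0, 1\]).
#' @param min_samples DBSCAN core-point threshold (default 5).
#'
#' @return A list of `consensus_version` objects (fields `labels`,
#'   `epsilon`, `n_clusters`, `outlier_fraction`), sorted by increasing
#'   `n_clusters`.
#' @export
consensus_partition <- function(ensemble,
                                epsilon_grid = seq(0.02, 1, length.out = 50),
                                min_samples = 5) {
  if (length(epsilon_grid) == 0) {
    mf_abort("`epsilon_grid` is empty.", "bad_argument")
  }
  d <- consensus_distance(ensemble)
  versions <- lapply(epsilon_grid, function(eps) {
    lab <- dbscan_precomputed(d, eps, min_samples)
    labels <- ifelse(lab == 0L, "OUTLIER", paste0("c", lab))
    names(labels) <- rownames(
      if (inherits(ensemble, "clustering_ensemble")) ensemble$assignments
      else ensemble
    )
    structure(
      list(labels = labels, epsilon = eps,
           n_clusters = length(setdiff(unique(labels), "OUTLIER")),
           outlier_fraction = mean(labels == "OUTLIER")),
      class = "consensus_version"
    )
  })
  versions[order(vapply(versions, `[[`, integer(1), "n_clusters"))]
}

#' @export
print.consensus_version <- function(x, ...) {
  cat(sprintf("<consensus_version> eps=%.3f, %d clusters, %.1f%% outliers\n",
              x$epsilon, x$n_clusters, 100 * x$outlier_fraction))
  invisible(x)
}

# ranger probability forest with inverse-class-size case weights
balanced_forest <- function(x, y, num_trees = 200, seed = 1L) {
  df <- data.frame(x, check.names = FALSE)
  df$.cls <- factor(y)
  w <- 1 / table(df$.cls)[df$.cls]
  with_seed(seed, {
    ranger::ranger(
      dependent.variable.name = ".cls", data = df, probability = TRUE,
      num.trees = num_trees, case.weights = as.numeric(w),
      importance = "impurity", seed = seed
    )
  })
}

forest_predict <- function(model, x) {
  predict(model, data = data.frame(x, check.names = FALSE))$predictions
}

#' Evaluate a consensus partition with a supervised reproducibility model
#'
#' Holds out a stratified fraction of cells, then on the remainder performs
#' recursive feature (component) elimination under cross-validation with a
#' class-imbalance-aware random forest, scoring each candidate component set
#' by cross-validated balanced accuracy. The best model is refit on the full
#' training split and scored on the untouched holdout.
#'
#' @param embedding Cell-by-component matrix (the clustering input).
#' @param labels Per-cell labels; `"OUTLIER"` cells are excluded.
#' @param holdout_fraction Held-out test fraction (default 0.1).
#' @param n_folds Cross-validation folds (default 10); reduced with a
#'   warning when a cluster is smaller than the fold count.
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#'
#' @return A list of class `partition_model` with `score` (holdout balanced
#'   accuracy), `model`, `features` (kept component indices), `classes`.
#' @export
evaluate_partition <- function(embedding, labels, holdout_fraction = 0.1,
                               n_folds = 10, seed = 1L, num_trees = 200) {
  embedding <- as.matrix(embedding)
  keep <- labels != "OUTLIER" & !is.na(labels)
  x <- embedding[keep, , drop = FALSE]
  y <- factor(as.character(labels[keep]))
  if (nlevels(y) < 2L) {
    mf_abort("Need at least two clusters to evaluate a partition.",
             "single_cluster")
  }
  min_size <- min(table(y))
  if (min_size < n_folds) {
    warn(sprintf("Smallest cluster (%d) below n_folds; using %d folds.",
                 min_size, max(2L, min_size)))
    n_folds <- max(2L, min_size)
  }

  with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, max(1L, round(holdout_fraction * length(idx))))
    }), use.names = FALSE)
  })
  train_idx <- setdiff(seq_along(y), test_idx)
  xtr <- x[train_idx, , drop = FALSE]
  ytr <- droplevels(y[train_idx])

  # component ranking from a forest on the full training split
  rank_model <- balanced_forest(xtr, ytr, num_trees, seed)
  ranking <- order(-rank_model$variable.importance)

  # candidate sets: halve the component count each step, floor 2
  sizes <- ncol(x)
  while (tail(sizes, 1) > 2) sizes <- c(sizes, max(2L, floor(tail(sizes, 1) / 2)))
  folds <- with_seed(seed + 1L, sample(rep_len(seq_len(n_folds), length(ytr))))
  cv_score <- vapply(sizes, function(sz) {
    feats <- ranking[seq_len(sz)]
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(ytr[tr])) < nlevels(ytr)) return(NA_real_)
      m <- balanced_forest(xtr[tr, feats, drop = FALSE], ytr[tr],
                           num_trees, seed + f)
      pr <- forest_predict(m, xtr[!tr, feats, drop = FALSE])
      balanced_accuracy(ytr[!tr], colnames(pr)[max.col(pr)])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))

  best <- sizes[which.max(cv_score)]
  features <- sort(ranking[seq_len(best)])
  final <- balanced_forest(xtr[, features, drop = FALSE], ytr,
                           num_trees, seed + 99L)
  pr <- forest_predict(final, x[test_idx, features, drop = FALSE])
  score <- balanced_accuracy(y[test_idx], colnames(pr)[max.col(pr)])
  structure(list(score = score, model = final, features = features,
                 classes = levels(ytr)),
            class = "partition_model")
}

#' Rescue outlier cells with the partition model
#'
#' Each outlier is assigned its predicted class when the maximum class
#' probability exceeds `prob_threshold`, otherwise it stays `"OUTLIER"`.
#'
#' @param fit A `partition_model` from [evaluate_partition()].
#' @param embedding Cell-by-component matrix (all cells).
#' @param labels Per-cell labels with `"OUTLIER"` entries to rescue.
#' @param prob_threshold Minimum prediction probability (default 0.5).
#' @return Labels with rescued outliers filled in.
#' @export
rescue_outliers <- function(fit, embedding, labels, prob_threshold = 0.5) {
  out_idx <- which(labels == "OUTLIER")
  if (length(out_idx) == 0) return(labels)
  pr <- forest_predict(fit$model,
                       embedding[out_idx, fit$features, drop = FALSE])
  best <- max.col(pr)
  pmax_ <- pr[cbind(seq_len(nrow(pr)), best)]
  rescued <- ifelse(pmax_ > prob_threshold, colnames(pr)[best], "OUTLIER")
  labels[out_idx] <- rescued
  labels
}

#' Select the clustering resolution satisfying all quality criteria
#'
#' Returns the maximum resolution whose consensus version keeps outliers
#' below `max_outlier_fraction`, scores above `min_score` in the supervised
#' evaluation, and keeps the mean cells-per-cluster at or above
#' `min_mean_cluster_size`.
#'
#' @param candidates A list of lists with fields `resolution`, `version`
#'   (a `consensus_version`), `score`.
#' @param max_outlier_fraction,min_score,min_mean_cluster_size Criteria
#'   (defaults 0.05, 0.95, 30).
#' @return The chosen resolution (numeric scalar).
#' @export
select_resolution <- function(candidates, max_outlier_fraction = 0.05,
                              min_score = 0.95, min_mean_cluster_size = 30) {
  if (length(candidates) == 0) mf_abort("No candidates.", "bad_argument")
  info <- purrr::map_dfr(candidates, function(cand) {
    v <- cand$version
    tibble::tibble(
      resolution = cand$resolution,
      outlier_fraction = v$outlier_fraction,
      score = cand$score,
      mean_cluster_size = sum(v$labels != "OUTLIER") / max(1L, v$n_clusters)
    )
  })
  ok <- info$outlier_fraction < max_outlier_fraction &
    info$score > min_score &
    info$mean_cluster_size >= min_mean_cluster_size
  if (!any(ok)) {
    msg <- paste0(
      "No resolution satisfies all criteria.\n",
      sprintf("  outlier_fraction >= %.3g: %s\n", max_outlier_fraction,
              paste(info$resolution[info$outlier_fraction >=
                                      max_outlier_fraction], collapse = ", ")),
      sprintf("  score <= %.3g: %s\n", min_score,
              paste(info$resolution[info$score <= min_score], collapse = ", ")),
      sprintf("  mean cluster size < %.3g: %s", min_mean_cluster_size,
              paste(info$resolution[info$mean_cluster_size <
                                      min_mean_cluster_size], collapse = ", "))
    )
    mf_abort(msg, "no_qualifying_resolution")
  }
  max(info$resolution[ok])
}

# one-vs-rest rank-sum statistics for every gene: returns AUC (P(in > rest))
# and a tie-corrected normal-approximation z-score
rank_sum_stats <- function(mat, in_cluster) {
  n1 <- sum(in_cluster)
  n2 <- sum(!in_cluster)
  n <- n1 + n2
  res <- apply(mat, 2, function(v) {
    r <- rank(v)
    u <- sum(r[in_cluster]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- if (sigma2 > 0) (u - n1 * n2 / 2) / sqrt(sigma2) else 0
    c(auc = u / (n1 * n2), z = z)
  })
  list(auc = unname(res["auc", ]), z = unname(res["z", ]))
}

#' One-versus-rest marker genes per cluster
#'
#' RNA markers are genes significantly higher in a cluster than in the rest
#' (rank-sum test with Benjamini-Hochberg adjustment, adjusted p < 0.01,
#' log2 fold-change > 1, AUROC > 0.8). Methylation markers use the reversed
#' direction (hypomethylation): adjusted p < 0.01, delta < -0.3, AUROC of
#' the *low* direction > 0.8, where delta is the cluster mean minus the mean
#' of the other clusters' per-cluster means.
#'
#' @param mat Cell-by-gene matrix: expression for `modality = "rna"`,
#'   normalized methylation rates for `"mch"`/`"mcg"`.
#' @param labels Per-cell cluster labels (`"OUTLIER"` cells are ignored).
#' @param modality One of `"rna"`, `"mch"`, `"mcg"`.
#' @param p_adj_max,min_lfc,max_delta,min_auroc Marker thresholds
#'   (defaults 0.01, 1, -0.3, 0.8).
#'
#' @return A tibble of class `marker_table`: one row per (cluster, gene)
#'   with `p`, `p_adj`, `effect`, `auroc`, `is_marker`.
#' @export
find_markers <- function(mat, labels, modality = c("rna", "mch", "mcg"),
                         p_adj_max = 0.01, min_lfc = 1, max_delta = -0.3,
                         min_auroc = 0.8) {
  modality <- match.arg(modality)
  mat <- as.matrix(mat)
  keep <- labels != "OUTLIER" & !is.na(labels)
  mat <- mat[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    mf_abort("Marker detection needs at least two clusters.",
             "single_cluster")
  }
  genes <- colnames(mat) %||% as.character(seq_len(ncol(mat)))

  cluster_means <- vapply(clusters, function(cl) {
    colMeans(mat[labels == cl, , drop = FALSE])
  }, numeric(ncol(mat)))

  rows <- lapply(clusters, function(cl) {
    in_cl <- labels == cl
    if (sum(in_cl) < 2L) {
      warn(sprintf("Cluster '%s' has fewer than 2 cells; skipped.", cl))
      return(NULL)
    }
    st <- rank_sum_stats(mat, in_cl)
    mean_in <- cluster_means[, cl]
    mean_rest_bycl <- rowMeans(cluster_means[, clusters != cl, drop = FALSE])
    if (modality == "rna") {
      p <- stats::pnorm(st$z, lower.tail = FALSE)  # higher in cluster
      eff <- log2((mean_in + 1e-9) / (colMeans(mat[!in_cl, , drop = FALSE]) +
                                        1e-9))
      auroc <- st$auc
      p_adj <- p.adjust(p, "BH")
      is_marker <- p_adj < p_adj_max & eff > min_lfc & auroc > min_auroc
    } else {
      p <- stats::pnorm(st$z)  # lower in cluster (hypomethylation)
      eff <- mean_in - mean_rest_bycl
      auroc <- 1 - st$auc
      p_adj <- p.adjust(p, "BH")
      is_marker <- p_adj < p_adj_max & eff < max_delta & auroc > min_auroc
    }
    tibble::tibble(cluster = cl, gene = genes, p = p, p_adj = p_adj,
                   effect = eff, auroc = auroc, is_marker = is_marker)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("marker_table", class(out))
  attr(out, "modality") <- modality
  out
}

#' Merge clusters lacking marker support into their nearest neighbor
#'
#' While any cluster has fewer than `min_markers` markers, the cluster with
#' the fewest markers is merged into the cluster with the nearest centroid
#' (Euclidean, in the clustering embedding space; ties broken toward the
#' larger cluster), and markers are recomputed. Stops when every cluster has
#' enough markers or a single cluster remains.
#'
#' @param labels Per-cell cluster labels.
#' @param mat Cell-by-gene matrix passed to [find_markers()].
#' @param embedding Cell-by-component matrix defining centroid space.
#' @param modality Marker modality (see [find_markers()]).
#' @param min_markers Minimum markers per cluster (default 10).
#' @param ... Further thresholds for [find_markers()].
#' @return Merged per-cell labels.
#' @export
merge_weak_clusters <- function(labels, mat, embedding,
                                modality = c("mch", "mcg", "rna"),
                                min_markers = 10, ...) {
  modality <- match.arg(modality)
  labels <- as.character(labels)
  repeat {
    clusters <- sort(setdiff(unique(labels), "OUTLIER"))
    if (length(clusters) < 2L) return(labels)
    mk <- find_markers(mat, labels, modality = modality, ...)
    counts <- vapply(clusters, function(cl) {
      sum(mk$is_marker[mk$cluster == cl])
    }, integer(1))
    if (all(counts >= min_markers)) return(labels)
    weak <- clusters[which.min(counts)]
    cent <- vapply(clusters, function(cl) {
      colMeans(embedding[labels == cl, , drop = FALSE])
    }, numeric(ncol(embedding)))
    d <- sqrt(colSums((cent - cent[, weak])^2))
    d[weak] <- Inf
    sizes <- table(factor(labels, levels = clusters))
    target <- clusters[order(d, -as.numeric(sizes))][1]
    labels[labels == weak] <- target
  }
}
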