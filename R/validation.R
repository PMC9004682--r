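#' Co-embed two modalities by canonical correlation analysis
#'
#' Columns (genes) of both matrices are standardized (zero mean, unit
#' variance; genes with zero variance in either matrix are dropped from
#' both), and the cross-product `X Y^T` is decomposed by truncated SVD.
#' The left singular vectors are coordinates for the X-side cells, the right
#' singular vectors for the Y-side cells, in a shared space. The two cell
#' sets may differ (e.g. for fusion); for paired data they share the index.
#'
#' @param x,y Cell-by-gene matrices with aligned gene columns.
#' @param n_components Components to keep (default 20); reduced with a
#'   warning when the cross-product has lower rank.
#' @param reverse_x Orient `x` against `y` by replacing it with
#'   `max(x) - x` before standardization. Use this when `x` is methylation
#'   and `y` expression: gene-body mCH is anti-correlated with expression,
#'   and without reversal the two cell clouds land on opposite sides of the
#'   shared space.
#' @param scale_by_singular_values Multiply each component by the square
#'   root of its singular value (default `TRUE`), so that components are
#'   weighted by the strength of cross-modal covariation they capture;
#'   `FALSE` returns the orthonormal singular vectors.
#'
#' @return A list of class `coembedding` with `u` (X cells x components),
#'   `v` (Y cells x components) and `singular_values`. Sign convention: the
#'   largest-magnitude entry of each column of `u` is positive.
#' @export
cca_coembed <- function(x, y, n_components = 20, reverse_x = FALSE,
                        scale_by_singular_values = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (reverse_x) x <- max(x) - x
  if (ncol(x) != ncol(y)) mf_abort("Gene columns must align.", "bad_argument")
  if (ncol(x) == 0) mf_abort("No shared genes.", "bad_argument")
  sx <- apply(x, 2, sd); sy <- apply(y, 2, sd)
  keep <- sx > 0 & sy > 0
  x <- scale(x[, keep, drop = FALSE])
  y <- scale(y[, keep, drop = FALSE])
  m <- tcrossprod(x, y)
  k <- min(n_components, dim(m))
  s <- if (min(dim(m)) > k + 2) irlba::irlba(m, nv = k) else {
    ss <- svd(m, nu = k, nv = k)
    list(u = ss$u, v = ss$v, d = ss$d[seq_len(k)])
  }
  pos <- s$d > max(s$d) * 1e-8
  if (sum(pos) < n_components) {
    warn(sprintf("Rank %d below requested %d components; returning %d.",
                 sum(pos), n_components, sum(pos)))
  }
  u <- s$u[, pos, drop = FALSE]
  v <- s$v[, pos, drop = FALSE]
  if (scale_by_singular_values) {
    w <- sqrt(s$d[pos])
    u <- u %*% diag(w, length(w))
    v <- v %*% diag(w, length(w))
  }
  fixed <- fix_svd_signs(u, v)
  rownames(fixed$u) <- rownames(x)
  rownames(fixed$v) <- rownames(y)
  structure(list(u = fixed$u, v = fixed$v, singular_values = s$d[pos]),
            class = "coembedding")
}

#' @export
print.coembedding <- function(x, ...) {
  cat(sprintf("<coembedding> %d x-cells, %d y-cells, %d components\n",
              nrow(x$u), nrow(x$v), ncol(x$u)))
  invisible(x)
}

#' Cross-modality k-partners
#'
#' For each X-side cell, the `k` nearest Y-side cells by Euclidean distance
#' in the co-embedding, sorted by distance with ties broken by ascending
#' cell index.
#'
#' @param embedding A [cca_coembed()] result.
#' @param k Partners per cell; at most the number of Y-side cells.
#' @return Integer matrix, one row per X cell, `k` ordered Y indices.
#' @export
cross_modal_partners <- function(embedding, k) {
  d <- cross_dist(embedding$u, embedding$v)
  if (k > ncol(d)) mf_abort("`k` exceeds the number of Y-side cells.",
                            "bad_argument")
  t(apply(d, 1, function(row) order(row, seq_along(row))[seq_len(k)]))
}

#' Per-cluster over-splitting score
#'
#' For each cluster `C`, every member's `|C|` cross-modal partners are
#' inspected; the score is the fraction of those partners that fall outside
#' `C`: `S_over = 1 - (1/|C|^2) * sum_i sum_{j in P_i(|C|)} 1[label_j = C]`.
#' 0 means no over-splitting (all partners stay inside), 1 means none do.
#'
#' @param embedding A [cca_coembed()] of paired cells (shared index).
#' @param labels Per-cell cluster labels on that shared index.
#' @return A tibble with `cluster`, `size`, `s_over`.
#' @export
over_splitting_score <- function(embedding, labels) {
  labels <- as.character(labels)
  n <- nrow(embedding$u)
  stopifnot(length(labels) == n)
  d <- cross_dist(embedding$u, embedding$v)
  ord <- t(apply(d, 1, function(row) order(row, seq_along(row))))
  clusters <- sort(unique(labels))
  out <- purrr::map_dfr(clusters, function(cl) {
    idx <- which(labels == cl)
    k <- min(length(idx), n)
    inside <- sum(vapply(idx, function(i) {
      sum(labels[ord[i, seq_len(k)]] == cl)
    }, numeric(1)))
    tibble::tibble(cluster = cl, size = length(idx),
                   s_over = 1 - inside / length(idx)^2)
  })
  class(out) <- c("split_scores", class(out))
  out
}

#' Per-cell self-radii from a co-embedding
#'
#' The self-radius of cell `i` is the number of cross-modal cells whose
#' profiles are closer to cell `i`'s X-profile than its own Y-profile is:
#' `r_i = #\{j != i : d_ij < d_ii\}`. Small radii mean the two modalities
#' agree on the cell; within a homogeneous cluster the radii should be
#' uniform between 0 and the cluster size.
#'
#' @param embedding A [cca_coembed()] of paired cells.
#' @return Integer vector of radii, one per cell.
#' @export
self_radii <- function(embedding) {
  d <- cross_dist(embedding$u, embedding$v)
  self <- diag(d)
  vapply(seq_len(nrow(d)), function(i) {
    sum(d[i, -i] < self[i])
  }, integer(1))
}

#' Per-cluster under-splitting score
#'
#' Within a cluster `C` the normalized self-radius is `rho_i = r_i / |C|`;
#' the score is the slope of its cumulative distribution at `quantile`:
#' `S_under = P(rho <= quantile) / quantile`. For an ideal (homogeneous)
#' cluster the radii are uniform and the score is 1; an under-split cluster
#' concentrates small radii and scores above 1.
#'
#' @param radii Per-cell self-radii (from [self_radii()]).
#' @param labels Per-cell cluster labels, aligned with `radii`.
#' @param quantile Evaluation point of the CDF slope (default 0.25).
#' @return A tibble with `cluster`, `size`, `s_under`.
#' @export
under_splitting_score <- function(radii, labels, quantile = 0.25) {
  labels <- as.character(labels)
  stopifnot(length(radii) == length(labels))
  clusters <- sort(unique(labels))
  out <- purrr::map_dfr(clusters, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 0) mf_abort("Empty cluster.", "bad_argument")
    rho <- radii[idx] / length(idx)
    tibble::tibble(cluster = cl, size = length(idx),
                   s_under = mean(rho <= quantile) / quantile)
  })
  class(out) <- c("split_scores", class(out))
  out
}

#' Shuffle gene profiles within clusters to build an ideal reference
#'
#' Within each cluster, every gene column is permuted independently across
#' the cluster's cells, separately in each modality. Per-gene, per-cluster
#' marginals are preserved exactly while per-cell cross-modal coupling is
#' destroyed, yielding homogeneous clusters with no under-splitting.
#'
#' @param features_x,features_y Cell-by-gene matrices on a shared index.
#' @param labels Per-cell cluster labels.
#' @param seed Integer seed.
#' @return A list with shuffled `x` and `y` matrices.
#' @export
make_ideal_reference <- function(features_x, features_y, labels, seed = 1L) {
  shuffle_one <- function(mat) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      for (g in seq_len(ncol(mat))) {
        mat[idx, g] <- mat[idx[sample.int(length(idx))], g]
      }
    }
    mat
  }
  with_seed(seed, {
    list(x = shuffle_one(as.matrix(features_x)),
         y = shuffle_one(as.matrix(features_y)))
  })
}

#' AIC- and BIC-like criteria for a cluster-centroid model
#'
#' Under a Gaussian cell-around-centroid model with shared variance,
#' `AIC = train_mse + 2 d sigma^2 / N` and
#' `BIC = train_mse + log(N) d sigma^2 / N`, with `d` the number of
#' clusters, `N` the number of cells and `sigma^2` the dataset variance
#' under the single-cluster assumption (mean per-feature variance).
#'
#' @param train_mse Training mean squared error.
#' @param n Number of cells.
#' @param d Number of clusters (model dimension).
#' @param sigma2 Dataset variance.
#' @return Named numeric vector `c(aic = ..., bic = ...)`.
#' @export
#'
#' @examples
#' information_criteria(0.5, n = 100, d = 5, sigma2 = 1)
information_criteria <- function(train_mse, n, d, sigma2) {
  assert_count(n, "n")
  assert_count(d, "d")
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    mf_abort("`sigma2` must be positive.", "bad_argument")
  }
  c(aic = train_mse + 2 * d * sigma2 / n,
    bic = train_mse + log(n) * d * sigma2 / n)
}

# mean squared deviation of cells from their cluster centroids
centroid_mse <- function(mat, labels, centroids, global_mean) {
  sq <- vapply(seq_len(nrow(mat)), function(i) {
    cl <- labels[i]
    cen <- if (cl %in% rownames(centroids)) centroids[cl, ] else global_mean
    mean((mat[i, ] - cen)^2)
  }, numeric(1))
  mean(sq)
}

#' Cross-validated cluster-number error curve across modalities
#'
#' Cells are clustered at several granularities on one modality (Leiden on
#' the top principal components), and each clustering is scored on the
#' *other* modality: cluster centroids are estimated from a training fold
#' and the mean squared error of held-out cells against their centroid is
#' recorded. AIC/BIC are computed from the training error of each
#' replicate. The test error is minimized near the true number of
#' distinguishable populations, while training error decreases
#' monotonically.
#'
#' @param cluster_modality Cell-by-feature matrix used for clustering.
#' @param eval_modality Matching matrix used for evaluation.
#' @param resolutions Leiden resolutions to traverse.
#' @param n_folds Cross-validation folds (default 5).
#' @param n_seeds Clustering repeats per resolution (default 5).
#' @param n_pcs Principal components for clustering (default 20).
#' @param k KNN graph size (default 25).
#' @param seed Base seed.
#'
#' @return A tibble of class `validation_curve`, one row per
#'   (resolution, clustering seed, fold): `resolution`, `rep`, `fold`,
#'   `n_clusters`, `train_mse`, `test_mse`, `aic`, `bic`.
#' @export
cv_error_curve <- function(cluster_modality, eval_modality, resolutions,
                           n_folds = 5, n_seeds = 5, n_pcs = 20, k = 25,
                           seed = 1L) {
  cluster_modality <- as.matrix(cluster_modality)
  eval_modality <- as.matrix(eval_modality)
  stopifnot(nrow(cluster_modality) == nrow(eval_modality))
  n <- nrow(eval_modality)
  pcs <- embed_methylome(cluster_modality, n_pcs = n_pcs)
  g <- knn_graph(pcs, k)
  sigma2 <- mean(apply(eval_modality, 2, var))
  global_mean <- colMeans(eval_modality)

  rows <- list()
  for (ri in seq_along(resolutions)) {
    for (s in seq_len(n_seeds)) {
      lab <- as.character(leiden_cluster(graph = g,
                                         resolution = resolutions[ri],
                                         seed = seed + 1000L * ri + s))
      d_clusters <- length(unique(lab))
      folds <- with_seed(seed + 7L * ri + 131L * s,
                         sample(rep_len(seq_len(n_folds), n)))
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        centroids <- do.call(rbind, lapply(split(which(tr), lab[tr]), function(i) {
          colMeans(eval_modality[i, , drop = FALSE])
        }))
        tmse <- centroid_mse(eval_modality[tr, , drop = FALSE], lab[tr],
                             centroids, global_mean)
        vmse <- centroid_mse(eval_modality[!tr, , drop = FALSE], lab[!tr],
                             centroids, global_mean)
        # zero-variance evaluation data: penalty term is identically zero
        ic <- if (sigma2 > 0) {
          information_criteria(tmse, n = sum(tr), d = d_clusters,
                               sigma2 = sigma2)
        } else c(aic = tmse, bic = tmse)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          resolution = resolutions[ri], rep = s, fold = f,
          n_clusters = d_clusters, train_mse = tmse, test_mse = vmse,
          aic = ic[["aic"]], bic = ic[["bic"]]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("validation_curve", class(out))
  out
}

# Leiden with resolution bisected toward a target cluster count
leiden_target_clusters <- function(coords, target, k = 30, seed = 1L,
                                   max_iter = 20) {
  g <- knn_graph(coords, k)
  lo <- 1e-3; hi <- 10
  best <- NULL; best_gap <- Inf
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    lab <- as.integer(leiden_cluster(graph = g, resolution = mid, seed = seed))
    nc <- length(unique(lab))
    gap <- abs(nc - target)
    if (gap < best_gap) {
      best <- list(labels = lab, resolution = mid, n_clusters = nc)
      best_gap <- gap
    }
    if (nc == target) break
    if (nc < target) lo <- mid else hi <- mid
  }
  if (best$n_clusters != target) {
    warn(sprintf("Bisection reached %d co-clusters (target %d).",
                 best$n_clusters, target))
  }
  best
}

#' Fusion quality metrics: rank self-radius, mis-fusion ratio, accuracy
#'
#' For each cell with profiles in both modalities, the rank `d` of its
#' Y-profile among the neighbors of its X-profile over all `2N` joint rows
#' (self excluded, ranks from 1) gives the normalized rank self-radius
#' `d / 2N`. Cells with normalized radius above `misfusion_threshold` count
#' as mis-fused. Joint Leiden co-clusters (resolution bisected to hit
#' `target_n_coclusters`) give the co-cluster accuracy: the fraction of
#' cells whose two profiles land in the same co-cluster.
#'
#' @param joint_coords Matrix of joint coordinates, one row per profile
#'   (2N rows).
#' @param cell_pairs Two-column matrix/data frame of row indices: X-profile
#'   and Y-profile of each cell.
#' @param misfusion_threshold Normalized-radius cutoff (default 0.3).
#' @param target_n_coclusters Desired number of co-clusters.
#' @param k KNN graph size for co-clustering (default 30).
#' @param seed Integer seed.
#'
#' @return A list of class `fusion_metrics`: `per_cell` tibble (`rank`,
#'   `normalized_radius`, `co_clustered`), `mis_fusion_ratio`,
#'   `cocluster_accuracy`, `coclusters`, `resolution`.
#' @export
evaluate_fusion <- function(joint_coords, cell_pairs,
                            misfusion_threshold = 0.3,
                            target_n_coclusters = NULL, k = 30, seed = 1L) {
  joint_coords <- as.matrix(joint_coords)
  cp <- as.matrix(cell_pairs)
  if (any(cp < 1) || any(cp > nrow(joint_coords))) {
    mf_abort("`cell_pairs` indices outside the joint matrix.",
             "bad_argument")
  }
  n2 <- nrow(joint_coords)
  d <- cross_dist(joint_coords[cp[, 1], , drop = FALSE], joint_coords)
  ranks <- vapply(seq_len(nrow(cp)), function(i) {
    dv <- d[i, ]
    sum(dv[-cp[i, 1]] < dv[cp[i, 2]]) + 1L
  }, integer(1))
  normalized <- ranks / n2
  mis <- mean(normalized > misfusion_threshold)

  coclusters <- NULL; accuracy <- NA_real_; res <- NA_real_
  co_same <- rep(NA, nrow(cp))
  if (!is.null(target_n_coclusters)) {
    fit <- leiden_target_clusters(joint_coords, target_n_coclusters, k, seed)
    coclusters <- fit$labels
    res <- fit$resolution
    co_same <- coclusters[cp[, 1]] == coclusters[cp[, 2]]
    accuracy <- mean(co_same)
  }
  structure(
    list(per_cell = tibble::tibble(rank = ranks,
                                   normalized_radius = normalized,
                                   co_clustered = co_same),
         mis_fusion_ratio = mis, cocluster_accuracy = accuracy,
         coclusters = coclusters, resolution = res),
    class = "fusion_metrics"
  )
}

#' Overlap score between two cluster labelings through a co-clustering
#'
#' For clusters `a` (from labeling A) and `b` (from labeling B),
#' `score(a, b) = sum_g min(|a intersect g| / |a|, |b intersect g| / |b|)`
#' over co-clusters `g`. 1 means the two clusters are consistently
#' co-clustered; 0 means they never share a co-cluster.
#'
#' @param labels_a,labels_b Named vectors of cluster labels (names are cell
#'   ids; the two cell sets may be disjoint or shared).
#' @param coclusters Named vector of co-cluster assignments covering every
#'   cell in `labels_a` and `labels_b`.
#' @return Numeric matrix, clusters of A by clusters of B.
#' @export
overlap_score <- function(labels_a, labels_b, coclusters) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)) ||
      is.null(names(coclusters))) {
    mf_abort("All labelings must be named by cell id.", "bad_argument")
  }
  if (!all(c(names(labels_a), names(labels_b)) %in% names(coclusters))) {
    mf_abort("`coclusters` must cover every cell.", "bad_argument")
  }
  cls_a <- sort(unique(as.character(labels_a)))
  cls_b <- sort(unique(as.character(labels_b)))
  gs <- sort(unique(as.character(coclusters)))
  prop <- function(labels, cls) {
    m <- vapply(gs, function(g) {
      in_g <- names(labels)[coclusters[names(labels)] == g]
      vapply(cls, function(cl) {
        idx <- names(labels)[labels == cl]
        if (length(idx) == 0) mf_abort("Empty cluster.", "bad_argument")
        length(intersect(idx, in_g)) / length(idx)
      }, numeric(1))
    }, numeric(length(cls)))
    if (!is.matrix(m)) m <- matrix(m, nrow = length(cls))
    m
  }
  pa <- prop(labels_a, cls_a)  # cls_a x gs
  pb <- prop(labels_b, cls_b)
  out <- matrix(0, length(cls_a), length(cls_b),
                dimnames = list(cls_a, cls_b))
  for (g in seq_along(gs)) {
    out <- out + outer(pa[, g], pb[, g], pmin)
  }
  out
}
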