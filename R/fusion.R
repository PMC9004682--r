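#' Within-modality diffusion smoothing operator
#'
#' On the kNN graph of the cells a Gaussian kernel is applied to the
#' distances, with a per-cell bandwidth `sigma_i` equal to the distance to
#' the `ka`-th neighbor. The kernel matrix (zero diagonal, zero outside the
#' kNN) is symmetrized by addition, row-normalized, and mixed with the
#' identity: `W = p I + (1 - p) A`, so `p` controls how much of a cell's
#' smoothed profile comes from itself.
#'
#' @param coords Cell-by-component matrix (typically top PCs).
#' @param k Neighbors in the kNN graph (default 30).
#' @param ka Bandwidth neighbor (default 5), must be below `k`.
#' @param p Self weight in \[0,1\]: 0.9 is used for methylation, 0.7 for RNA.
#'
#' @return A list of class `smoothing_operator` with `weights` (sparse
#'   row-stochastic matrix), `k`, `ka`, `p`.
#' @export
build_smoothing_operator <- function(coords, k = 30, ka = 5, p = 0.9) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!(ka < k && k < n)) {
    mf_abort("Need ka < k < n_cells.", "bad_argument")
  }
  assert_scalar_number(p, "p", 0, 1)
  nn <- RANN::nn2(coords, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  dst <- nn$nn.dists[, -1, drop = FALSE]
  sigma <- dst[, ka]
  zero_sigma <- sigma == 0
  if (any(zero_sigma)) {
    warn(sprintf("%d cell(s) with duplicate neighbors; using the smallest positive neighbor distance as bandwidth.",
                 sum(zero_sigma)))
    for (i in which(zero_sigma)) {
      pos <- dst[i, dst[i, ] > 0]
      sigma[i] <- if (length(pos) > 0) min(pos) else 1
    }
  }
  w <- exp(-dst^2 / sigma^2)
  a1 <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(idx), x = as.vector(w),
    dims = c(n, n)
  )
  a2 <- a1 + Matrix::t(a1)
  a3 <- a2 / Matrix::rowSums(a2)
  weights <- p * Matrix::Diagonal(n) + (1 - p) * a3
  structure(list(weights = weights, k = k, ka = ka, p = p),
            class = "smoothing_operator")
}

#' Diffuse a feature matrix through a smoothing operator
#'
#' @param features Cell-by-gene matrix.
#' @param op A [build_smoothing_operator()] result.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_features <- function(features, op) {
  stopifnot(inherits(op, "smoothing_operator"))
  features <- as.matrix(features)
  if (nrow(features) != nrow(op$weights)) {
    mf_abort("Feature matrix and operator disagree on cell count.",
             "bad_argument")
  }
  out <- as.matrix(op$weights %*% features)
  dimnames(out) <- dimnames(features)
  out
}

#' Restricted k-partners: capacity-constrained cross-modal matching
#'
#' In `k` rounds, source cells are visited in a fresh seeded random order
#' and each connects to its nearest *eligible* target; a target that has
#' accumulated `k' = ceiling(z k N_source / N_target)` partners leaves the
#' pool, so no target can serve more than `z` times the average load. Each
#' source never reuses a target, ending with `k` distinct partners. With
#' `z = 1` every target ends with exactly `k'` or `k' - 1` partners.
#'
#' @param source_coords,target_coords Coordinate (or feature, for the
#'   correlation metric) matrices for the two modalities.
#' @param k Partners per source cell.
#' @param z Capacity relaxation, `>= 1` (default 3).
#' @param seed Integer seed for the per-round orders.
#' @param metric `"euclidean"` on coordinates, or `"one_minus_spearman"`
#'   treating rows as feature profiles.
#'
#' @return A list of class `partner_graph` with `partners` (source-by-k
#'   integer matrix, columns in round order), `k`, `k_prime`, `z`,
#'   `target_counts`.
#' @export
restricted_k_partners <- function(source_coords, target_coords, k, z = 3,
                                  seed = 1L,
                                  metric = c("euclidean",
                                             "one_minus_spearman")) {
  metric <- match.arg(metric)
  if (z < 1) mf_abort("`z` must be at least 1.", "bad_argument")
  src <- as.matrix(source_coords)
  tgt <- as.matrix(target_coords)
  ns <- nrow(src); nt <- nrow(tgt)
  assert_count(k, "k")
  if (k > nt) mf_abort("`k` exceeds the number of target cells.",
                       "bad_argument")
  d <- switch(metric,
    euclidean = cross_dist(src, tgt),
    one_minus_spearman = 1 - stats::cor(t(src), t(tgt), method = "spearman")
  )
  k_prime <- ceiling(z * k * ns / nt)
  # per-source target preference lists, ties by ascending index
  pref <- t(apply(d, 1, function(row) order(row, seq_along(row))))
  pos <- rep(1L, ns)            # lazily advancing pointer into pref
  used <- matrix(FALSE, ns, nt) # targets already taken by each source
  count <- integer(nt)
  eligible <- rep(TRUE, nt)
  partners <- matrix(NA_integer_, ns, k)
  with_seed(seed, {
    for (round in seq_len(k)) {
      for (i in sample.int(ns)) {
        while (pos[i] <= nt) {
          cand <- pref[i, pos[i]]
          if (eligible[cand] && !used[i, cand]) break
          pos[i] <- pos[i] + 1L
        }
        if (pos[i] > nt) {
          mf_abort("A source cell ran out of eligible targets.",
                   "infeasible")
        }
        cand <- pref[i, pos[i]]
        partners[i, round] <- cand
        used[i, cand] <- TRUE
        count[cand] <- count[cand] + 1L
        if (count[cand] >= k_prime) eligible[cand] <- FALSE
      }
    }
  })
  structure(list(partners = partners, k = k, k_prime = k_prime, z = z,
                 target_counts = count),
            class = "partner_graph")
}

#' Impute cross-modality features by partner averaging
#'
#' @param graph A [restricted_k_partners()] result.
#' @param target_features Smoothed cell-by-gene matrix of the target
#'   modality.
#' @return Source-cell-by-gene matrix: the unweighted mean of each source
#'   cell's partners' feature vectors.
#' @export
impute_cross_modality <- function(graph, target_features) {
  stopifnot(inherits(graph, "partner_graph"))
  target_features <- as.matrix(target_features)
  if (max(graph$partners) > nrow(target_features)) {
    mf_abort("Partner id outside the target feature matrix.",
             "bad_argument")
  }
  out <- matrix(0, nrow(graph$partners), ncol(target_features))
  for (r in seq_len(ncol(graph$partners))) {
    out <- out + target_features[graph$partners[, r], , drop = FALSE]
  }
  out <- out / ncol(graph$partners)
  colnames(out) <- colnames(target_features)
  out
}

#' Transfer cluster labels across modalities by partner majority
#'
#' A source cell receives label `L` when at least `majority` of its
#' partners carry `L`; otherwise it is `"UNASSIGNED"`. When two labels tie
#' exactly at the threshold, the label with more partners across the whole
#' graph wins, then lexicographic order.
#'
#' @param graph A [restricted_k_partners()] result.
#' @param target_labels Labels for every target cell.
#' @param majority Required partner fraction (default 0.5).
#' @return Character vector of per-source labels.
#' @export
transfer_labels <- function(graph, target_labels, majority = 0.5) {
  target_labels <- as.character(target_labels)
  if (max(graph$partners) > length(target_labels)) {
    mf_abort("Labels missing for some targets.", "bad_argument")
  }
  global_counts <- table(target_labels[as.vector(graph$partners)])
  apply(graph$partners, 1, function(pp) {
    tab <- table(target_labels[pp])
    frac <- tab / length(pp)
    cand <- names(frac)[frac >= majority]
    if (length(cand) == 0) return("UNASSIGNED")
    if (length(cand) > 1) {
      gc <- as.numeric(global_counts[cand])
      cand <- cand[order(-gc, cand)]
    }
    cand[1]
  })
}

#' Fuse a methylome and a transcriptome dataset into one embedding
#'
#' End-to-end integration: restrict to shared genes, orient methylation
#' against expression (`max - value`), smooth each modality on its own PC
#' kNN graph, co-embed by CCA, match source cells to target cells with
#' restricted k-partners, impute the target modality's features for the
#' source cells, then embed all cells together (PCA of the stacked
#' measured + imputed features) and cluster jointly with Leiden.
#'
#' By default the modality with fewer cells is the source (its missing
#' features are imputed from the larger, target, modality); ties make the
#' methylome the target.
#'
#' @param mch Cell-by-gene normalized mCH matrix.
#' @param rna Cell-by-gene normalized expression matrix (aligned columns or
#'   shared column names).
#' @param shared_genes Gene names to use; defaults to the intersection of
#'   column names.
#' @param k,z Restricted k-partner parameters (defaults 30, 3).
#' @param p_meth,p_rna Smoothing self-weights (defaults 0.9, 0.7).
#' @param n_cca CCA components (default 50).
#' @param n_pcs Joint PCA components (default 50).
#' @param resolution Leiden resolution for joint clustering (default 1).
#' @param k_cluster KNN size for the joint graph (default 30).
#' @param seed Integer seed.
#' @param umap If `TRUE` and the uwot package is installed, also compute a
#'   UMAP of the joint PCs (n_neighbors 30, min_dist 0.5).
#'
#' @return A list of class `fusion_result` with `coords` (joint PC matrix,
#'   methylome rows first), `labels`, `cells` (tibble with `row`, `cell`,
#'   `modality`), `partner_graph`, `coembedding`, optional `umap`.
#' @export
fuse_datasets <- function(mch, rna, shared_genes = NULL, k = 30, z = 3,
                          p_meth = 0.9, p_rna = 0.7, n_cca = 50, n_pcs = 50,
                          resolution = 1, k_cluster = 30, seed = 1L,
                          umap = FALSE) {
  mch <- as.matrix(mch); rna <- as.matrix(rna)
  if (is.null(shared_genes)) {
    shared_genes <- intersect(colnames(mch), colnames(rna))
  }
  if (length(shared_genes) == 0) mf_abort("No shared genes.", "bad_argument")
  x <- mch[, shared_genes, drop = FALSE]
  y <- rna[, shared_genes, drop = FALSE]
  if (all(x == 0) || all(y == 0)) {
    mf_abort("A feature block is identically zero.", "bad_argument")
  }
  x <- max(x) - x  # orient methylation with expression

  smooth_modality <- function(feat, p) {
    pcs <- embed_methylome(feat, n_pcs = min(50, ncol(feat), nrow(feat) - 1))
    op <- build_smoothing_operator(pcs, k = min(30, nrow(feat) - 2),
                                   ka = 5, p = p)
    smooth_features(feat, op)
  }
  xs <- smooth_modality(x, p_meth)
  ys <- smooth_modality(y, p_rna)

  ce <- cca_coembed(xs, ys, n_components = min(n_cca, nrow(xs), nrow(ys)))

  # source = smaller modality; target features are what gets stacked
  mch_is_target <- nrow(xs) >= nrow(ys)
  if (mch_is_target) {
    src_coords <- ce$v; tgt_coords <- ce$u; tgt_features <- xs
  } else {
    src_coords <- ce$u; tgt_coords <- ce$v; tgt_features <- ys
  }
  graph <- restricted_k_partners(src_coords, tgt_coords,
                                 k = min(k, nrow(tgt_coords)), z = z,
                                 seed = seed)
  imputed <- impute_cross_modality(graph, tgt_features)

  if (mch_is_target) {
    stacked <- rbind(xs, imputed)
    cells <- tibble::tibble(
      row = seq_len(nrow(xs) + nrow(ys)),
      cell = c(rownames(mch) %||% paste0("x", seq_len(nrow(xs))),
               rownames(rna) %||% paste0("y", seq_len(nrow(ys)))),
      modality = rep(c("mch", "rna"), c(nrow(xs), nrow(ys)))
    )
  } else {
    stacked <- rbind(imputed, ys)
    cells <- tibble::tibble(
      row = seq_len(nrow(xs) + nrow(ys)),
      cell = c(rownames(mch) %||% paste0("x", seq_len(nrow(xs))),
               rownames(rna) %||% paste0("y", seq_len(nrow(ys)))),
      modality = rep(c("mch", "rna"), c(nrow(xs), nrow(ys)))
    )
  }

  coords <- embed_methylome(stacked,
                            n_pcs = min(n_pcs, ncol(stacked),
                                        nrow(stacked) - 1))
  labels <- as.character(leiden_cluster(coords, resolution = resolution,
                                        k = k_cluster, seed = seed))
  um <- NULL
  if (umap && requireNamespace("uwot", quietly = TRUE)) {
    um <- with_seed(seed, uwot::umap(coords, n_neighbors = 30,
                                     min_dist = 0.5))
  }
  structure(
    list(coords = coords, labels = labels, cells = cells,
         partner_graph = graph, coembedding = ce, umap = um,
         mch_is_target = mch_is_target),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d profiles, %d joint clusters\n",
              nrow(x$coords), length(unique(x$labels))))
  invisible(x)
}
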