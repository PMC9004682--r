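#' Filter genes for the mCH-RNA correlation analysis
#'
#' Keeps genes that are expressed in more than `min_expr_cell_fraction` of
#' cells and have cytosine coverage above `min_cov` in more than
#' `min_cov_cell_fraction` of cells.
#'
#' @param rna_counts Cell-by-gene RNA count matrix.
#' @param mch_cov Cell-by-gene cytosine coverage matrix (aligned genes).
#' @param min_expr_cell_fraction,min_cov,min_cov_cell_fraction Defaults
#'   0.01, 20, 0.95.
#' @return Logical gene mask.
#' @export
filter_genes_for_correlation <- function(rna_counts, mch_cov,
                                         min_expr_cell_fraction = 0.01,
                                         min_cov = 20,
                                         min_cov_cell_fraction = 0.95) {
  stopifnot(ncol(rna_counts) == ncol(mch_cov))
  expressed <- colMeans(as.matrix(rna_counts) > 0) > min_expr_cell_fraction
  covered <- colMeans(as.matrix(mch_cov) > min_cov) > min_cov_cell_fraction
  unname(expressed & covered)
}

#' Normalize RNA counts to log10(TPM + 1)
#'
#' With gene lengths, counts are divided by length before per-cell scaling
#' to one million; without lengths all genes are treated as equal length,
#' making the result log10(CPM + 1).
#'
#' @param counts Cell-by-gene non-negative count matrix.
#' @param gene_lengths Optional per-gene lengths.
#' @return Log-scale expression matrix; cells with zero total counts are
#'   dropped with a warning.
#' @export
normalize_expression <- function(counts, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) mf_abort("Counts must be non-negative.",
                                "bad_argument")
  rate <- if (is.null(gene_lengths)) counts
          else counts / rep(gene_lengths, each = nrow(counts))
  totals <- rowSums(rate)
  if (any(totals == 0)) {
    warn(sprintf("%d cell(s) with zero counts dropped.", sum(totals == 0)))
    rate <- rate[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  log10(rate / totals * 1e6 + 1)
}

#' Normalize gene-body mCH rates by each cell's global level
#'
#' @param mch_rates Cell-by-gene mCH rate matrix (fractions).
#' @param global_mch Per-cell global mCH level, strictly positive.
#' @return `mch_rates / global_mch` row-wise.
#' @export
normalize_gene_mch <- function(mch_rates, global_mch) {
  mch_rates <- as.matrix(mch_rates)
  stopifnot(length(global_mch) == nrow(mch_rates))
  if (any(global_mch <= 0)) {
    mf_abort("Global mCH must be positive for every cell.", "bad_argument")
  }
  mch_rates / global_mch
}

# per-gene Spearman correlations between aligned columns of two matrices,
# given pre-ranked, column-centered inputs
paired_column_cor <- function(rx, ry) {
  num <- colSums(rx * ry)
  den <- sqrt(colSums(rx^2) * colSums(ry^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Gene-level mCH-RNA coupling with an empirical shuffled null
#'
#' Computes the Spearman correlation of each gene's normalized gene-body
#' mCH with its expression across cells, then builds a null by shuffling
#' the cell correspondence between the two modalities `n_shuffles` times
#' (one permutation per shuffle, shared across genes, preserving
#' within-modality gene-gene structure). The empirical FDR of a rho
#' threshold is the mean null count of genes at least as extreme divided by
#' the observed count; per-gene q-values are monotonized over thresholds
#' and genes with `q < fdr` are flagged significant.
#'
#' @param mch_norm Cell-by-gene normalized mCH matrix.
#' @param expr Cell-by-gene expression matrix (aligned).
#' @param n_shuffles Null permutations (default 100).
#' @param fdr Significance level on the empirical FDR (default 0.05).
#' @param direction `"negative"` (default; mCH-repressed genes),
#'   `"positive"`, or `"both"` (two-sided on |rho|).
#' @param seed Integer seed.
#'
#' @return A tibble of class `correlation_table`: `gene`, `rho`, `p_emp`,
#'   `q`, `significant`, `direction`. Genes constant in either modality are
#'   returned with `rho = NA` and excluded from the calibration.
#' @export
correlate_genes <- function(mch_norm, expr, n_shuffles = 100, fdr = 0.05,
                            direction = c("negative", "positive", "both"),
                            seed = 1L) {
  direction <- match.arg(direction)
  mch_norm <- as.matrix(mch_norm)
  expr <- as.matrix(expr)
  stopifnot(identical(dim(mch_norm), dim(expr)))
  n <- nrow(expr)
  if (n < 3) mf_abort("Need at least 3 cells.", "bad_argument")
  genes <- colnames(expr) %||% as.character(seq_len(ncol(expr)))

  rx <- scale(apply(mch_norm, 2, rank), scale = FALSE)
  ry <- scale(apply(expr, 2, rank), scale = FALSE)
  rho <- paired_column_cor(rx, ry)

  null_rho <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      paired_column_cor(rx[sample.int(n), , drop = FALSE], ry)
    }, numeric(ncol(expr)))
  })

  # signed score: significance region is {score <= t}
  score <- switch(direction, negative = rho, positive = -rho, both = -abs(rho))
  null_score <- switch(direction, negative = null_rho,
                       positive = -null_rho, both = -abs(null_rho))
  ok <- !is.na(score)
  obs <- score[ok]
  nullv <- as.vector(null_score)
  nullv <- nullv[!is.na(nullv)]

  ord <- order(obs)
  sorted <- obs[ord]
  n_obs_le <- seq_along(sorted)
  n_null_le <- findInterval(sorted, sort(nullv)) / n_shuffles
  fdr_at <- pmin(1, n_null_le / n_obs_le)
  q_sorted <- rev(cummin(rev(fdr_at)))  # best FDR over enclosing regions
  q <- rep(NA_real_, length(score))
  q[ok][ord] <- q_sorted

  p_emp <- rep(NA_real_, length(score))
  p_emp[ok] <- (1 + findInterval(obs, sort(nullv))) / (1 + length(nullv))

  out <- tibble::tibble(
    gene = genes, rho = rho, p_emp = p_emp, q = q,
    significant = !is.na(q) & q < fdr, direction = direction
  )
  class(out) <- c("correlation_table", class(out))
  attr(out, "n_shuffles") <- n_shuffles
  out
}

#' Fraction of per-gene variance explained by cluster identity
#'
#' `eta^2 = SS_between / SS_total`, with the between-cluster sum of squares
#' over cluster means weighted by cluster size.
#'
#' @param values Cell-by-gene matrix (expression or methylation).
#' @param labels Per-cell cluster labels; at least two clusters with at
#'   least two cells each.
#' @return A tibble with `gene`, `eta_sq`, `zero_variance`.
#' @export
eta_squared <- function(values, labels) {
  values <- as.matrix(values)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(values))
  clusters <- unique(labels)
  if (length(clusters) < 2L) {
    mf_abort("eta^2 needs at least two clusters.", "single_cluster")
  }
  if (any(table(labels) < 2L)) {
    mf_abort("Every cluster needs at least two cells.", "bad_argument")
  }
  grand <- colMeans(values)
  ss_total <- colSums(sweep(values, 2, grand)^2)
  ss_between <- Reduce(`+`, lapply(clusters, function(cl) {
    idx <- labels == cl
    sum(idx) * (colMeans(values[idx, , drop = FALSE]) - grand)^2
  }))
  zero <- ss_total == 0
  eta <- ifelse(zero, 0, ss_between / ss_total)
  tibble::tibble(
    gene = colnames(values) %||% as.character(seq_len(ncol(values))),
    eta_sq = unname(eta), zero_variance = unname(zero)
  )
}
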