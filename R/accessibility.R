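#' Binarize NOMe-seq GpC methylation into open/closed calls
#'
#' Models the GmCY basecalls of a bin in a cell as
#' `Binomial(cov, global)` with `global` the cell's genome-wide GmCY level,
#' and computes the probability of observing *equal or greater* methylated
#' calls than seen (the inclusive upper tail, i.e. the binomial survival
#' function evaluated at `observed - 1`). Bins with `p < p_threshold` are
#' called open (1), all others closed (0); zero-coverage bins are closed.
#'
#' @param gmcy Cell-by-bin matrix of methylated GCY basecalls.
#' @param gcy_cov Matching matrix of total GCY basecalls.
#' @param global_rates Per-cell global GmCY level, strictly inside (0,1).
#' @param p_threshold Tail-probability cutoff (default 0.05).
#'
#' @return A list of class `binary_accessibility` with `values` (cell-by-bin
#'   0/1 matrix) and `global_rates`.
#' @export
#'
#' @examples
#' binarize_accessibility(matrix(10), matrix(10), global_rates = 0.5)$values
binarize_accessibility <- function(gmcy, gcy_cov, global_rates,
                                   p_threshold = 0.05) {
  gmcy <- as.matrix(gmcy); gcy_cov <- as.matrix(gcy_cov)
  stopifnot(identical(dim(gmcy), dim(gcy_cov)),
            length(global_rates) %in% c(1L, nrow(gmcy)))
  if (any(gmcy > gcy_cov)) {
    mf_abort("Need gmcy <= gcy_cov element-wise.", "bad_argument")
  }
  if (any(global_rates <= 0 | global_rates >= 1)) {
    mf_abort("Global GmCY rates must lie strictly in (0,1).",
             "degenerate_rate")
  }
  global_rates <- rep_len(global_rates, nrow(gmcy))
  # P(X >= obs) = survival at obs - 1; obs = 0 gives p = 1
  p <- matrix(
    pbinom(as.vector(gmcy) - 1, as.vector(gcy_cov),
           rep(global_rates, ncol(gmcy)), lower.tail = FALSE),
    nrow(gmcy), ncol(gmcy)
  )
  values <- (p < p_threshold) * 1L
  values[gcy_cov == 0] <- 0L
  dimnames(values) <- dimnames(gmcy)
  structure(list(values = values, global_rates = global_rates),
            class = "binary_accessibility")
}

#' Latent semantic analysis of a binary accessibility matrix
#'
#' Filters bins open in too few cells and bins with extreme column sums,
#' then applies log-term-frequency LSA: rows of the filtered 0/1 matrix `A`
#' are normalized by their row sums to `B`, each entry transformed as
#' `log(B + 1) * log(1 + n_cells / colsum_j(A))`, and the result decomposed
#' by truncated SVD. The first `n_dims` left singular vectors (cells) are
#' returned, sign-fixed so the largest-magnitude entry of each vector is
#' positive.
#'
#' @param binary A `binary_accessibility` object or a 0/1 cell-by-bin matrix.
#' @param min_cells_open Keep only bins open in more than this many cells
#'   (default 10).
#' @param colsum_zmax Remove bins whose z-scored column sum is at or above
#'   this bound (default 2), computed after the min-cells filter.
#' @param n_dims Number of singular vectors to return (default 15).
#' @param scale_by_singular_values If `TRUE`, multiply each component by its
#'   singular value.
#'
#' @return Cell-by-component coordinate matrix with attribute
#'   `"singular_values"`.
#' @export
lsa_embed <- function(binary, min_cells_open = 10, colsum_zmax = 2,
                      n_dims = 15, scale_by_singular_values = FALSE) {
  a <- if (inherits(binary, "binary_accessibility")) binary$values
       else as.matrix(binary)
  if (!all(a %in% c(0, 1))) {
    mf_abort("Input must be a 0/1 matrix.", "bad_argument")
  }
  n_cells <- nrow(a)
  cs <- colSums(a)
  keep <- cs > min_cells_open
  a <- a[, keep, drop = FALSE]
  cs <- cs[keep]
  if (length(cs) > 1 && sd(cs) > 0) {
    zkeep <- (cs - mean(cs)) / sd(cs) < colsum_zmax
    a <- a[, zkeep, drop = FALSE]
    cs <- cs[zkeep]
  }
  if (ncol(a) == 0L) {
    mf_abort("All bins removed by filtering; nothing to embed.",
             "empty_matrix")
  }
  rs <- rowSums(a)
  if (any(rs == 0)) {
    warn(sprintf("%d cell(s) with no open bins dropped before LSA.",
                 sum(rs == 0)))
    a <- a[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  b <- a / rs
  idf <- log(1 + n_cells / cs)
  cmat <- log1p(b) * rep(idf, each = nrow(b))
  n_dims <- min(n_dims, ncol(cmat), nrow(cmat) - 1L)
  sv <- if (min(dim(cmat)) > n_dims + 2) {
    irlba::irlba(cmat, nv = n_dims)
  } else {
    s <- svd(cmat, nu = n_dims, nv = n_dims)
    list(u = s$u, v = s$v, d = s$d[seq_len(n_dims)])
  }
  fixed <- fix_svd_signs(sv$u, sv$v)
  out <- if (scale_by_singular_values) {
    fixed$u %*% diag(sv$d[seq_len(n_dims)], n_dims)
  } else fixed$u
  rownames(out) <- rownames(a)
  attr(out, "singular_values") <- sv$d[seq_len(n_dims)]
  out
}
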