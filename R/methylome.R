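#' Filter cells on mapping/QC metrics
#'
#' A cell passes when its bisulfite non-conversion proxy (mCCC rate) is low,
#' global mCG and mCH levels are in the plausible somatic range, and read
#' depth and mapping rate are sufficient.
#'
#' @param metrics Data frame with columns `mccc_rate`, `global_mcg`,
#'   `global_mch`, `total_reads`, `mapping_rate`.
#' @param max_mccc,min_global_mcg,max_global_mch,min_total_reads,min_mapping_rate
#'   Thresholds; defaults 0.03, 0.5, 0.2, 500000, 0.5. All comparisons are
#'   strict.
#'
#' @return Logical vector, `TRUE` for cells that pass.
#' @export
filter_cells <- function(metrics, max_mccc = 0.03, min_global_mcg = 0.5,
                         max_global_mch = 0.2, min_total_reads = 5e5,
                         min_mapping_rate = 0.5) {
  metrics <- as.data.frame(metrics)
  need <- c("mccc_rate", "global_mcg", "global_mch", "total_reads",
            "mapping_rate")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols) > 0) {
    mf_abort(paste0("Missing QC metric column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "missing_column")
  }
  metrics$mccc_rate < max_mccc &
    metrics$global_mcg > min_global_mcg &
    metrics$global_mch < max_global_mch &
    metrics$total_reads > min_total_reads &
    metrics$mapping_rate > min_mapping_rate
}

# zero-based half-open interval overlap (any shared base pair)
intervals_overlap <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

#' Filter genomic-bin features by mean coverage and blacklist overlap
#'
#' @param counts A [paired_counts].
#' @param min_mean_cov,max_mean_cov Inclusive bounds on the per-feature mean
#'   total basecalls; defaults 300/3000 (use 250/2500 for joint
#'   methylome+transcriptome assays).
#' @param blacklist Optional data frame of intervals (`chrom`, `start`,
#'   `end`, 0-based half-open); features overlapping any interval by at
#'   least one base pair are removed. Requires `feature_intervals` on
#'   `counts`.
#'
#' @return Logical feature mask, `TRUE` for kept features.
#' @export
filter_bins <- function(counts, min_mean_cov = 300, max_mean_cov = 3000,
                        blacklist = NULL) {
  stopifnot(inherits(counts, "paired_counts"))
  mean_cov <- colMeans(counts$cov)
  keep <- mean_cov >= min_mean_cov & mean_cov <= max_mean_cov
  if (!is.null(blacklist)) {
    if (is.null(counts$feature_intervals)) {
      mf_abort("Blacklist filtering needs `feature_intervals` on `counts`.",
               "bad_argument")
    }
    blacklist <- validate_intervals(blacklist)
    keep <- keep & !intervals_overlap(counts$feature_intervals, blacklist)
  }
  unname(keep)
}

#' Fit a per-cell beta-binomial prior by the method of moments
#'
#' With `m` and `v` the sample mean and variance of the raw rates `mc/cov`
#' over covered features, the beta shape parameters are
#' `alpha = m * (m * (1 - m) / v - 1)` and
#' `beta = (1 - m) * (m * (1 - m) / v - 1)`. Cells with noisier raw rates
#' (larger `v`) receive a weaker prior.
#'
#' @param rates Numeric vector of raw per-feature rates for one cell
#'   (features without coverage must already be excluded / `NA`).
#'
#' @return A list of class `betabinomial_prior` with `alpha`, `beta` and the
#'   prior mean `m = alpha / (alpha + beta)`.
#' @export
#'
#' @examples
#' fit_betabinomial_prior(c(0.7, 0.8, 0.9, 0.8))
fit_betabinomial_prior <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2L) {
    mf_abort("Need at least two covered features to fit a prior.",
             "bad_argument")
  }
  m <- mean(rates)
  v <- var(rates)
  if (v == 0) mf_abort("Raw rates are constant; prior undefined.",
                       "constant_rate")
  if (v >= m * (1 - m)) {
    mf_abort("Raw-rate variance >= m(1-m); method of moments invalid.",
             "degenerate_prior")
  }
  s <- m * (1 - m) / v - 1
  structure(list(alpha = m * s, beta = (1 - m) * s, m = m),
            class = "betabinomial_prior")
}

#' Beta-binomial posterior methylation rates, normalized per cell
#'
#' For each cell the posterior rate `(alpha + mc) / (alpha + beta + cov)` is
#' divided by the cell's prior mean `m = alpha / (alpha + beta)`, so a
#' feature with zero coverage maps to exactly 1 and low-coverage features
#' shrink toward 1. The output is dense with no missing values.
#'
#' @param counts A [paired_counts].
#' @param priors Optional list of [fit_betabinomial_prior()] results, one per
#'   cell; fitted from the covered raw rates of each cell when omitted.
#'
#' @return A cell-by-feature numeric matrix of normalized posterior rates.
#' @export
normalize_rates <- function(counts, priors = NULL) {
  stopifnot(inherits(counts, "paired_counts"))
  n <- nrow(counts$mc)
  if (is.null(priors)) {
    rr <- raw_rates(counts)
    priors <- lapply(seq_len(n), function(i) fit_betabinomial_prior(rr[i, ]))
  }
  if (length(priors) != n) {
    mf_abort("Need one prior per cell.", "bad_argument")
  }
  alpha <- vapply(priors, `[[`, numeric(1), "alpha")
  beta <- vapply(priors, `[[`, numeric(1), "beta")
  m <- alpha / (alpha + beta)
  post <- (alpha + counts$mc) / (alpha + beta + counts$cov)
  out <- post / m
  dimnames(out) <- dimnames(counts$mc)
  out
}

#' Select highly variable features within mean-by-coverage bins
#'
#' Features are assigned to a 2-D grid of (mean normalized rate, mean
#' coverage) bins; the dispersion (variance/mean) of each feature is
#' z-scored within its bin, and the `n_top` features with the highest
#' normalized dispersion are returned. Binning removes the dependence of
#' dispersion on both the mean methylation level and the sequencing depth of
#' a feature. Bins with a single feature contribute a z-score of 0.
#'
#' @param rates Cell-by-feature normalized rate matrix
#'   (from [normalize_rates()]).
#' @param cov Matching coverage matrix.
#' @param n_top Number of features to return (default 3000).
#' @param n_mean_bins,n_cov_bins Grid resolution (defaults 20 x 5).
#'
#' @return Integer vector of feature indices ordered by decreasing
#'   normalized dispersion; ties broken by ascending index. The full
#'   per-feature table is attached as attribute `"dispersion"`.
#' @export
select_variable_features <- function(rates, cov, n_top = 3000,
                                     n_mean_bins = 20, n_cov_bins = 5) {
  stopifnot(identical(dim(rates), dim(cov)))
  p <- ncol(rates)
  if (n_top > p) mf_abort("`n_top` exceeds the number of features.",
                          "bad_argument")
  fmean <- colMeans(rates)
  fvar <- apply(rates, 2, var)
  dispersion <- ifelse(fmean > 0, fvar / fmean, 0)
  mcov <- colMeans(cov)

  cut_idx <- function(x, nb) {
    if (diff(range(x)) == 0) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = nb, include.lowest = TRUE))
  }
  bin <- paste(cut_idx(fmean, n_mean_bins), cut_idx(mcov, n_cov_bins))

  z <- numeric(p)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) < 2L || sd(dispersion[idx]) == 0) {
      z[idx] <- 0
    } else {
      z[idx] <- (dispersion[idx] - mean(dispersion[idx])) / sd(dispersion[idx])
    }
  }
  ord <- order(-z, seq_len(p))
  out <- ord[seq_len(n_top)]
  attr(out, "dispersion") <- tibble::tibble(
    feature = seq_len(p), mean = fmean, mean_cov = mcov,
    dispersion = dispersion, dispersion_z = z
  )
  out
}

#' Scale selected features and embed by PCA
#'
#' Each selected feature is z-scored across cells (no clipping) and the
#' top principal components are returned. The component count is an explicit
#' parameter: inspecting the variance-ratio elbow is a manual step, so the
#' chosen value must be supplied (default 20).
#'
#' @param rates Normalized rate matrix.
#' @param features Feature indices (e.g. from [select_variable_features()]).
#' @param n_pcs Number of components (default 20).
#' @return Cell-by-component score matrix.
#' @export
embed_methylome <- function(rates, features = seq_len(ncol(rates)),
                            n_pcs = 20) {
  x <- rates[, features, drop = FALSE]
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  x <- scale(x)
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  pr <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  pr$x
}
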