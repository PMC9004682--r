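#' Paired methylated/total call matrices for one sequence context
#'
#' The basic container for single-cell methylation data: a cell-by-feature
#' matrix of methylated basecalls (`mc`) and a matching matrix of total
#' basecalls (`cov`), for one sequence context such as `HCH` (endogenous
#' non-CG methylation), `HCG` (CG methylation) or `GCY` (GpC accessibility
#' signal from NOMe-seq).
#'
#' @param mc Cell-by-feature matrix of methylated basecalls (non-negative
#'   integers).
#' @param cov Cell-by-feature matrix of total basecalls, same shape as `mc`,
#'   with `cov >= mc` element-wise.
#' @param context Character label for the sequence context, e.g. `"HCH"`.
#' @param feature_intervals Optional data frame of genomic intervals for the
#'   features with columns `chrom`, `start`, `end` (0-based, half-open),
#'   one row per feature column.
#'
#' @return An object of class `paired_counts` with elements `mc`, `cov`,
#'   `context`, `feature_intervals`.
#' @export
#'
#' @examples
#' pc <- paired_counts(matrix(0:3, 2), matrix(4, 2, 2), context = "HCH")
#' dim(pc)
paired_counts <- function(mc, cov, context = "HCH", feature_intervals = NULL) {
  mc <- as.matrix(mc)
  cov <- as.matrix(cov)
  if (!identical(dim(mc), dim(cov))) {
    mf_abort("`mc` and `cov` must have the same dimensions.", "bad_argument")
  }
  if (any(mc < 0) || any(cov < 0) || any(mc > cov)) {
    mf_abort("Counts must be non-negative with mc <= cov element-wise.",
             "bad_argument")
  }
  if (!is.null(feature_intervals)) {
    feature_intervals <- validate_intervals(feature_intervals)
    if (nrow(feature_intervals) != ncol(mc)) {
      mf_abort("`feature_intervals` must have one row per feature.",
               "bad_argument")
    }
  }
  structure(
    list(mc = mc, cov = cov, context = as.character(context),
         feature_intervals = feature_intervals),
    class = "paired_counts"
  )
}

validate_intervals <- function(x) {
  x <- as.data.frame(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    mf_abort("Intervals need columns chrom, start, end.", "bad_argument")
  }
  if (any(x$end <= x$start)) {
    mf_abort("Malformed intervals: end must exceed start (0-based half-open).",
             "bad_argument")
  }
  x
}

#' @export
dim.paired_counts <- function(x) dim(x$mc)

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("<paired_counts> %d cells x %d features, context %s\n",
              nrow(x$mc), ncol(x$mc), x$context))
  invisible(x)
}

#' Subset a paired count matrix by cells and/or features
#'
#' @param x A [paired_counts] object.
#' @param i,j Cell and feature indices (any base subscript type).
#' @param ... Ignored.
#' @export
`[.paired_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$mc))
  if (missing(j)) j <- seq_len(ncol(x$mc))
  paired_counts(
    x$mc[i, j, drop = FALSE], x$cov[i, j, drop = FALSE], x$context,
    if (!is.null(x$feature_intervals)) {
      jj <- seq_len(ncol(x$mc))[j]
      x$feature_intervals[jj, , drop = FALSE]
    }
  )
}

#' Raw methylation rate matrix mc/cov
#'
#' @param x A [paired_counts] object.
#' @param fill Value used where `cov` is zero (default `NA`).
#' @return A cell-by-feature numeric matrix.
#' @export
raw_rates <- function(x, fill = NA_real_) {
  r <- x$mc / x$cov
  r[x$cov == 0] <- fill
  r
}
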