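#' Write a matrix as an MTX bundle with TSV sidecars
#'
#' Writes `<prefix>.mtx` (MatrixMarket sparse format) plus
#' `<prefix>.rows.tsv` and `<prefix>.cols.tsv` holding the dimnames.
#'
#' @param mat Matrix (dense or sparse).
#' @param dir Output directory (created if needed).
#' @param prefix File name stem.
#' @return The `.mtx` path, invisibly.
#' @export
write_mtx_bundle <- function(mat, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  path <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(sp, path)
  writeLines(rownames(mat) %||% as.character(seq_len(nrow(mat))),
             file.path(dir, paste0(prefix, ".rows.tsv")))
  writeLines(colnames(mat) %||% as.character(seq_len(ncol(mat))),
             file.path(dir, paste0(prefix, ".cols.tsv")))
  invisible(path)
}

#' Read a matrix written by [write_mtx_bundle()]
#'
#' @param dir Directory holding the bundle.
#' @param prefix File name stem.
#' @return A dense matrix with dimnames restored.
#' @export
read_mtx_bundle <- function(dir, prefix) {
  m <- as.matrix(Matrix::readMM(file.path(dir, paste0(prefix, ".mtx"))))
  rownames(m) <- readLines(file.path(dir, paste0(prefix, ".rows.tsv")))
  colnames(m) <- readLines(file.path(dir, paste0(prefix, ".cols.tsv")))
  m
}

#' Read a BED file of genomic intervals
#'
#' Minimal three-plus-column BED reader (0-based, half-open), returning a
#' tibble with `chrom`, `start`, `end` (+ `name` when present).
#'
#' @param path Path to a BED file.
#' @return A tibble of intervals.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  tibble::as_tibble(validate_intervals(x[, 1:min(4, ncol(x))]))
}

# one-upstream-base context patterns: H = A/C/T, Y = C/T
context_matches <- function(context, pattern) {
  classes <- c(H = "[ACT]", Y = "[CT]", C = "C", G = "G", A = "A", T = "T",
               N = "[ACGT]")
  chars <- strsplit(pattern, "")[[1]]
  regex <- paste0("^", paste(classes[chars], collapse = ""))
  grepl(regex, context)
}

#' Read an ALLC-style per-cytosine methylation table
#'
#' Tab-separated columns `chrom`, `pos`, `strand`, `context`, `mc`, `cov`
#' (no header). The context column carries one upstream base so that
#' GpC positions (exogenous accessibility signal) can be separated from
#' HpC positions (endogenous methylation).
#'
#' @param path Path to the TSV.
#' @param context_filter Optional context pattern such as `"HCH"`, `"HCG"`,
#'   `"GCY"`, `"HCY"` (H = A/C/T, Y = C/T).
#' @return A tibble of positions.
#' @export
read_allc <- function(path, context_filter = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "pos", "strand", "context",
                                       "mc", "cov"),
                         stringsAsFactors = FALSE)
  x <- tibble::as_tibble(x)
  if (!is.null(context_filter)) {
    x <- x[context_matches(x$context, context_filter), ]
  }
  x
}

#' Aggregate ALLC positions into interval features
#'
#' Sums `mc` and `cov` of every cytosine falling in each interval
#' (0-based half-open; ALLC positions are 1-based).
#'
#' @param allc A tibble from [read_allc()].
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @return A tibble, one row per interval, with `mc` and `cov`.
#' @export
aggregate_allc <- function(allc, intervals) {
  intervals <- validate_intervals(intervals)
  res <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    hit <- allc$chrom == intervals$chrom[i] &
      allc$pos - 1 >= intervals$start[i] & allc$pos - 1 < intervals$end[i]
    tibble::tibble(chrom = intervals$chrom[i], start = intervals$start[i],
                   end = intervals$end[i],
                   mc = sum(allc$mc[hit]), cov = sum(allc$cov[hit]))
  })
  res
}
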