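#' @importFrom rlang %||% abort warn .data
#' @importFrom stats var sd quantile rbinom rpois rnbinom rbeta runif rnorm
#'   pbinom p.adjust cor prcomp predict setNames plogis median
#' @importFrom utils head tail
NULL

# stop with a classed condition so callers/tests can match on class
mf_abort <- function(msg, class) {
  rlang::abort(msg, class = paste0("methylfusion_", class))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    mf_abort(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      "bad_argument"
    )
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    mf_abort(sprintf("`%s` must be an integer >= %d.", name, min),
             "bad_argument")
  }
  invisible(as.integer(x))
}

# run expr with a locally-set RNG state, leaving the caller's stream untouched
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# row-wise Euclidean distances between two coordinate matrices (n x d, m x d)
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# deterministic SVD sign convention: largest-|.| element of each left vector
# positive; the matching right vector is flipped with it
fix_svd_signs <- function(u, v) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  list(u = u, v = v)
}

balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}
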