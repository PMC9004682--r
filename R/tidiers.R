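#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a read partition into one row per class
#'
#' @param x A [partition_reads()] result.
#' @param ... Ignored.
#' @return A tibble with `class`, `n`, `fraction`.
#' @method tidy read_partition
#' @export
tidy.read_partition <- function(x, ...) x$summary

#' One-row summary of a read partition
#' @param x A [partition_reads()] result.
#' @param ... Ignored.
#' @method glance read_partition
#' @export
glance.read_partition <- function(x, ...) {
  tibble::tibble(
    n_reads = sum(x$summary$n),
    dna_fraction = x$summary$fraction[x$summary$class == "DNA"],
    rna_fraction = x$summary$fraction[x$summary$class == "RNA"],
    ambiguous_fraction = x$summary$fraction[x$summary$class == "ambiguous"]
  )
}

#' Tidy a consensus version into one row per cell
#' @param x A `consensus_version`.
#' @param ... Ignored.
#' @method tidy consensus_version
#' @export
tidy.consensus_version <- function(x, ...) {
  tibble::tibble(cell = names(x$labels) %||%
                   as.character(seq_along(x$labels)),
                 label = unname(x$labels))
}

#' One-row summary of a consensus version
#' @param x A `consensus_version`.
#' @param ... Ignored.
#' @method glance consensus_version
#' @export
glance.consensus_version <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, n_clusters = x$n_clusters,
                 outlier_fraction = x$outlier_fraction)
}

#' One-row summary of a supervised partition model
#' @param x A [evaluate_partition()] result.
#' @param ... Ignored.
#' @method glance partition_model
#' @export
glance.partition_model <- function(x, ...) {
  tibble::tibble(score = x$score, n_features = length(x$features),
                 n_classes = length(x$classes))
}

#' Tidy a beta-binomial prior
#' @param x A [fit_betabinomial_prior()] result.
#' @param ... Ignored.
#' @method tidy betabinomial_prior
#' @export
tidy.betabinomial_prior <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, m = x$m)
}

#' Tidy a fusion result into one row per profile
#' @param x A [fuse_datasets()] result.
#' @param ... Ignored.
#' @method tidy fusion_result
#' @export
tidy.fusion_result <- function(x, ...) {
  dplyr::mutate(x$cells, label = x$labels)
}

#' One-row summary of fusion metrics
#' @param x An [evaluate_fusion()] result.
#' @param ... Ignored.
#' @method glance fusion_metrics
#' @export
glance.fusion_metrics <- function(x, ...) {
  tibble::tibble(mis_fusion_ratio = x$mis_fusion_ratio,
                 cocluster_accuracy = x$cocluster_accuracy,
                 median_normalized_radius =
                   stats::median(x$per_cell$normalized_radius))
}
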