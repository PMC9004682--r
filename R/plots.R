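#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_histogram
#'   stat_summary labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a cross-validation error curve
#'
#' Mean train/test MSE (and AIC/BIC) against the realized number of
#' clusters, averaged over replicates.
#'
#' @param object A [cv_error_curve()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot validation_curve
#' @export
autoplot.validation_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("train_mse", "test_mse", "aic", "bic"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$n_clusters, y = .data$value,
                   colour = .data$metric)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point") +
    labs(x = "number of clusters", y = "error / criterion",
         colour = NULL) +
    theme_minimal()
}

#' Plot per-cluster over-/under-splitting scores
#'
#' @param object A tibble from [over_splitting_score()] or
#'   [under_splitting_score()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot split_scores
#' @export
autoplot.split_scores <- function(object, ...) {
  value_col <- intersect(c("s_over", "s_under"), names(object))[1]
  ggplot(object, aes(x = .data$cluster, y = .data[[value_col]],
                     size = .data$size)) +
    geom_point() +
    labs(y = value_col) +
    theme_minimal()
}

#' Histogram of gene-level coupling correlations
#'
#' @param object A [correlate_genes()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot correlation_table
#' @export
autoplot.correlation_table <- function(object, ...) {
  ggplot(dplyr::filter(object, !is.na(.data$rho)),
         aes(x = .data$rho, fill = .data$significant)) +
    geom_histogram(bins = 50) +
    labs(x = "Spearman rho (mCH vs RNA)", y = "genes") +
    theme_minimal()
}

#' Scatter plot of an embedding colored by labels
#'
#' @param coords Cell-by-component matrix (first two components used).
#' @param labels Optional per-cell labels.
#' @param dims Which two components to plot.
#' @return A ggplot.
#' @export
plot_embedding <- function(coords, labels = NULL, dims = c(1, 2)) {
  df <- tibble::tibble(
    d1 = coords[, dims[1]], d2 = coords[, dims[2]],
    label = if (is.null(labels)) "all" else as.character(labels)
  )
  ggplot(df, aes(x = .data$d1, y = .data$d2, colour = .data$label)) +
    geom_point(size = 0.8) +
    labs(x = paste0("dim ", dims[1]), y = paste0("dim ", dims[2]),
         colour = NULL) +
    theme_minimal()
}

#' Plot a fused embedding split by modality
#'
#' @param object A [fuse_datasets()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fusion_result
#' @export
autoplot.fusion_result <- function(object, ...) {
  coords <- if (!is.null(object$umap)) object$umap else object$coords
  df <- dplyr::mutate(object$cells,
                      d1 = coords[, 1], d2 = coords[, 2],
                      label = object$labels)
  ggplot(df, aes(x = .data$d1, y = .data$d2, colour = .data$label)) +
    geom_point(size = 0.8) +
    facet_wrap(~modality) +
    labs(colour = NULL) +
    theme_minimal()
}
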