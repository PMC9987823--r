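# ggplot2 visualizations of the package's result types.

#' Plot a cluster-count sweep
#'
#' AMI and ARI against the anatomy as a function of the number of K-means
#' clusters.
#'
#' @param object A [sweep_k()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("ami", "ari"),
                            names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$value,
                                   color = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "clusters (K)", y = "agreement with anatomy",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a compression trace
#'
#' Parcellation fidelity (AMI/ARI vs. the full-data parcellation and vs.
#' the anatomy) as the retained gene set shrinks.
#'
#' @param object A [compress_iteratively()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.compression_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, -"gene_ids"),
    c("ami_vs_full", "ari_vs_full", "ami_vs_truth", "ari_vs_truth"),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes_retained,
                                   y = .data$value, color = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "genes retained", y = "agreement", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-feature metric suite
#'
#' One panel per metric, features ordered by Dice.
#'
#' @param object A [feature_report()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_feature,
    c("dice", "n_connected_components", "feature_sparsity",
      "weight_sparsity", "shannon_entropy", "spatial_entropy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "feature", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a feature or label volume
#'
#' @param C A [component_set()].
#' @param k Feature index.
#' @param z 0-based z-slice to show (default: middle in-mask slice).
#' @param dims Grid dimensions (defaults to the coordinate bounding box).
#' @return A ggplot.
#' @export
plot_feature_slice <- function(C, k = 1L, z = NULL, dims = NULL) {
  df <- dplyr::bind_cols(C$coords, tibble(value = C$features[, k]))
  z <- z %||% stats::median(df$z)
  df <- df[df$z == z, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0("feature ", k, ", z = ", z)) +
    ggplot2::theme_minimal()
}
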