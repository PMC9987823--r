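# broom-style tidiers for the package's result objects.

#' Tidy a component set
#'
#' @param x A [component_set()].
#' @param matrix Which matrix to tidy: `"features"` (per-voxel activations)
#'   or `"weights"` (per-gene loadings).
#' @param ... Unused.
#' @return A long tibble: `voxel`/`x`/`y`/`z` (or `gene`), `component`,
#'   `value`.
#' @exportS3Method generics::tidy
tidy.component_set <- function(x, matrix = c("features", "weights"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "weights") {
    if (is.null(x$weights)) abort("this component set has no gene weights")
    df <- dplyr::bind_cols(tibble(gene = x$gene_ids), as_tibble(x$weights))
    return(tidyr::pivot_longer(df, -"gene", names_to = "component",
                               values_to = "value"))
  }
  df <- dplyr::bind_cols(x$coords, as_tibble(x$features))
  tidyr::pivot_longer(df, -c("x", "y", "z"), names_to = "component",
                      values_to = "value")
}

#' @exportS3Method generics::glance
glance.component_set <- function(x, ...) {
  tibble(
    method = x$method, k = ncol(x$features),
    n_voxels = nrow(x$features),
    n_genes = if (is.null(x$weights)) NA_integer_ else nrow(x$weights),
    objective = if (is.null(x$objective_trace)) NA_real_ else
      x$objective_trace[length(x$objective_trace)],
    iterations = if (is.null(x$objective_trace)) NA_integer_ else
      length(x$objective_trace) - 1L,
    seed = x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.parcellation <- function(x, ...) {
  dplyr::bind_cols(x$coords, tibble(label = x$labels))
}

#' @exportS3Method generics::glance
glance.parcellation <- function(x, ...) {
  tibble(k = x$K, n_voxels = length(x$labels), inertia = x$inertia,
         source = x$source, seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.feature_metric_report <- function(x, ...) x$per_feature

#' @exportS3Method generics::glance
glance.feature_metric_report <- function(x, ...) {
  as_tibble(x$aggregates)
}

#' @exportS3Method generics::tidy
tidy.probe_panel <- function(x, ...) {
  tibble(fold = seq_along(x$fold_auroc), auroc = x$fold_auroc,
         auprc = x$fold_auprc)
}

#' @exportS3Method generics::glance
glance.probe_panel <- function(x, ...) {
  tibble(region = x$region, n_genes = length(x$gene_ids),
         mean_auroc = x$mean_auroc, mean_auprc = x$mean_auprc,
         pooled_auprc = x$pooled_auprc, base_rate = x$base_rate,
         folds = x$folds, seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.phantom <- function(x, ...) {
  dplyr::bind_cols(x$expression$coords,
                   tibble(label = labels_at(x$annotation, x$expression$coords)))
}
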