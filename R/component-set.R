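#' Construct a component set
#'
#' Container for the output of a decomposition: a gene-by-K weight matrix
#' (loadings; `NULL` for methods that expose none, e.g. kernel PCA), a
#' voxel-by-K feature (activation) matrix, the method name, hyperparameters
#' and seed, plus the voxel coordinates and gene ids of the source matrix.
#'
#' @param weights Gene-by-K numeric matrix, or `NULL` if the method exposes
#'   no gene loadings.
#' @param features Voxel-by-K numeric matrix of activations.
#' @param method Method name string.
#' @param hyperparams Named list of hyperparameters.
#' @param seed Integer seed used by the fit.
#' @param objective_trace Optional numeric vector of per-iteration objective
#'   values (sparse filtering only).
#' @param gene_ids Character vector of gene ids.
#' @param coords Tibble of 0-based voxel coordinates.
#' @return An object of class `component_set`.
#' @export
component_set <- function(weights, features, method, hyperparams = list(),
                          seed = NA_integer_, objective_trace = NULL,
                          gene_ids = NULL, coords = NULL) {
  features <- as.matrix(features)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (ncol(weights) != ncol(features)) {
      abort("weights and features must have the same number of columns")
    }
  }
  if (!is.null(coords) && nrow(coords) != nrow(features)) {
    abort("features row count must equal the voxel count")
  }
  structure(
    list(weights = weights, features = features, method = method,
         hyperparams = hyperparams, seed = seed,
         objective_trace = objective_trace,
         gene_ids = gene_ids %||% rownames(weights),
         coords = coords),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> method=", x$method, ", K=", ncol(x$features),
      ", ", nrow(x$features), " voxels",
      if (is.null(x$weights)) ", no gene weights" else
        paste0(", ", nrow(x$weights), " genes"),
      "\n", sep = "")
  invisible(x)
}

n_components <- function(C) ncol(C$features)

#' Write / read a component set as a directory
#'
#' `weights.tsv` (gene id + one column per component; omitted when the
#' method exposes no loadings), `features.tsv` (voxel coordinates + one
#' column per component) and `meta.json` (method, hyperparameters, seed,
#' objective trace).
#'
#' @param C A [component_set()].
#' @param dir Directory path.
#' @return `write_component_set` returns `dir` invisibly;
#'   `read_component_set` returns a `component_set`.
#' @export
write_component_set <- function(C, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(C$weights)) {
    wdf <- dplyr::bind_cols(tibble(gene = rownames(C$weights)),
                            as_tibble(C$weights))
    readr::write_tsv(wdf, file.path(dir, "weights.tsv"))
  }
  fdf <- dplyr::bind_cols(C$coords, as_tibble(C$features))
  readr::write_tsv(fdf, file.path(dir, "features.tsv"))
  meta <- list(method = C$method, hyperparams = C$hyperparams,
               seed = C$seed, objective_trace = C$objective_trace,
               K = ncol(C$features))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_component_set
#' @export
read_component_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  fdf <- readr::read_tsv(file.path(dir, "features.tsv"), show_col_types = FALSE)
  coords <- fdf[, c("x", "y", "z")]
  features <- as.matrix(fdf[, setdiff(names(fdf), c("x", "y", "z")), drop = FALSE])
  weights <- NULL
  gene_ids <- NULL
  wpath <- file.path(dir, "weights.tsv")
  if (file.exists(wpath)) {
    wdf <- readr::read_tsv(wpath, show_col_types = FALSE)
    gene_ids <- wdf$gene
    weights <- as.matrix(wdf[, -1, drop = FALSE])
    rownames(weights) <- gene_ids
  }
  component_set(
    weights = weights, features = features, method = meta$method,
    hyperparams = as.list(meta$hyperparams), seed = meta$seed,
    objective_trace = meta$objective_trace,
    gene_ids = gene_ids, coords = coords
  )
}
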