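#' Construct a voxel-by-gene expression matrix
#'
#' The central data container of the package: a dense matrix of expression
#' values with one row per in-mask voxel and one column per gene, together
#' with the 0-based integer grid coordinate of every voxel. After
#' [ztransform()] the values are dimensionless z-scores; before it they are
#' raw expression energies (arbitrary units, nonnegative).
#'
#' @param values Numeric matrix, voxels in rows and genes in columns.
#' @param coords Data frame with integer columns `x`, `y`, `z` (0-based grid
#'   coordinates), one row per voxel. No duplicates allowed.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to the column names of `values`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `coords` (tibble) and `gene_ids`.
#' @export
expression_matrix <- function(values, coords, gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("`values` must be a numeric matrix")
  coords <- as_tibble(coords)
  if (!all(c("x", "y", "z") %in% names(coords))) {
    abort("`coords` must have columns x, y, z")
  }
  coords <- coords[, c("x", "y", "z")]
  if (nrow(coords) != nrow(values)) {
    abort("`coords` must have one row per voxel row of `values`")
  }
  if (anyDuplicated(coords)) abort("duplicated voxel coordinates")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(values)) {
    abort("`gene_ids` must have one entry per gene column")
  }
  if (anyDuplicated(gene_ids)) abort("duplicated gene ids")
  colnames(values) <- gene_ids
  rownames(values) <- NULL
  structure(
    list(values = values, coords = coords, gene_ids = gene_ids),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " voxels x ",
      ncol(x$values), " genes\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

n_voxels <- function(E) nrow(E$values)
n_genes <- function(E) ncol(E$values)

# Coerce a bare matrix (e.g. in unit tests) into an expression_matrix with
# synthetic line coordinates.
#' Coerce a matrix to an `expression_matrix`
#'
#' Rows become voxels laid out along the x axis; useful for small examples
#' and tests where geometry is irrelevant.
#'
#' @param x Numeric matrix (voxels x genes) or an `expression_matrix`.
#' @return An `expression_matrix`.
#' @export
as_expression_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  x <- as.matrix(x)
  expression_matrix(
    x,
    tibble(x = seq_len(nrow(x)) - 1L, y = 0L, z = 0L),
    gene_ids = colnames(x) %||% sprintf("g%04d", seq_len(ncol(x)))
  )
}

# Subset genes, preserving voxel rows and coordinates.
subset_genes <- function(E, gene_ids) {
  missing <- setdiff(gene_ids, E$gene_ids)
  if (length(missing)) {
    abort(paste0("genes not present: ", paste(head(missing, 5), collapse = ", ")))
  }
  expression_matrix(E$values[, gene_ids, drop = FALSE], E$coords, gene_ids)
}

#' Write / read the TSV matrix dialect
#'
#' The on-disk dialect is a plain TSV with a header row: the first three
#' columns `x`, `y`, `z` hold the 0-based voxel grid coordinates, the
#' remaining columns are genes (header = gene id).
#'
#' @param E An `expression_matrix`.
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(E, path) {
  df <- dplyr::bind_cols(E$coords, as_tibble(E$values))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  expression_matrix(
    as.matrix(df[, -(1:3), drop = FALSE]),
    df[, 1:3],
    gene_ids = names(df)[-(1:3)]
  )
}
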