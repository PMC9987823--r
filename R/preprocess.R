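#' Z-transform an expression matrix per gene
#'
#' Centers and scales every gene column so that across voxels the mean is 0
#' and the standard deviation is 1. The population convention (divide by n)
#' is used throughout so that the transform is exactly idempotent and
#' bit-stable. Voxel order and gene order are preserved.
#'
#' Constant (zero-variance) genes carry no spatial information and have no
#' z-score; by default they are dropped with a warning naming the genes, in
#' strict mode they raise an error.
#'
#' @param E An [expression_matrix()] (or bare matrix) of raw values.
#' @param strict If `TRUE`, a constant gene column is an error instead of
#'   being dropped.
#' @param quiet If `TRUE`, suppress the warning when constant columns are
#'   dropped.
#' @return An `expression_matrix` of z-scores, with any constant genes
#'   removed (default mode).
#' @export
ztransform <- function(E, strict = FALSE, quiet = FALSE) {
  E <- as_expression_matrix(E)
  X <- E$values
  if (!all(is.finite(X))) abort("non-finite values in expression matrix")
  n <- nrow(X)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(X^2) - mu^2)
  sdev[sdev < 0] <- 0  # numeric guard
  constant <- sdev < 1e-12
  if (any(constant)) {
    bad <- E$gene_ids[constant]
    if (strict) {
      abort(paste0("constant gene column(s): ", paste(head(bad, 10), collapse = ", ")))
    }
    if (!quiet) {
      warn(paste0("dropping ", length(bad), " constant gene column(s): ",
                  paste(head(bad, 10), collapse = ", ")))
    }
    X <- X[, !constant, drop = FALSE]
    mu <- mu[!constant]
    sdev <- sdev[!constant]
  }
  if (ncol(X) == 0L) abort("no genes left after dropping constant columns")
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  expression_matrix(Z, E$coords, colnames(X))
}

#' Consistency-based gene filter across paired experiments
#'
#' Ranks genes by the Pearson correlation of their expression across voxels
#' between two paired matrices (e.g. two replicate experiment series on the
#' same grid) and removes the least consistent fraction. Genes whose
#' correlation is undefined (constant in either matrix) rank last.
#'
#' @param a,b Paired [expression_matrix()] objects sharing gene ids and the
#'   same voxel grid.
#' @param drop_fraction Fraction of genes to remove, in `[0, 1)`. The
#'   survivor count is `ceiling(n_genes * (1 - drop_fraction))`.
#' @return Character vector of retained gene ids, ordered by decreasing
#'   correlation; ties broken by gene id order in `a`.
#' @export
consistency_filter <- function(a, b, drop_fraction = 0.25) {
  a <- as_expression_matrix(a)
  b <- as_expression_matrix(b)
  check_scalar_number(drop_fraction, "drop_fraction", min = 0, max = 1 - 1e-12)
  sym_diff <- c(setdiff(a$gene_ids, b$gene_ids), setdiff(b$gene_ids, a$gene_ids))
  if (length(sym_diff)) {
    abort(paste0("gene sets differ; symmetric difference: ",
                 paste(head(sym_diff, 10), collapse = ", ")))
  }
  if (nrow(a$values) != nrow(b$values)) abort("voxel grids differ in size")
  Xb <- b$values[, a$gene_ids, drop = FALSE]
  cors <- vapply(seq_along(a$gene_ids), function(j) {
    x <- a$values[, j]
    y <- Xb[, j]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  rank_key <- ifelse(is.na(cors), -Inf, cors)
  ord <- order(-rank_key, seq_along(rank_key))
  n_keep <- ceiling(length(ord) * (1 - drop_fraction))
  a$gene_ids[ord[seq_len(n_keep)]]
}
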