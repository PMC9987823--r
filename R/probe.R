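#' Top genes of a feature by absolute weight
#'
#' The `n` genes with the largest absolute weights, in descending order;
#' ties break by gene id order. All-zero weights are fully degenerate and
#' emit a warning (the first `n` genes in id order are returned).
#'
#' @param w Named per-gene weight vector (names = gene ids), or an unnamed
#'   vector with `gene_ids` supplied.
#' @param n Panel size (at most the gene count).
#' @param gene_ids Gene ids, if `w` is unnamed.
#' @return Character vector of `n` gene ids.
#' @export
top_genes <- function(w, n = 10L, gene_ids = names(w)) {
  n <- check_count(n, "n")
  if (is.null(gene_ids)) abort("gene ids are required")
  if (n > length(w)) abort("`n` exceeds the gene count")
  if (all(w == 0)) warn("all weights are zero: ranking is degenerate")
  gene_ids[order(-abs(w), seq_along(w))][seq_len(n)]
}

stratified_folds <- function(y, folds, seed) {
  idx <- seq_along(y)
  fold_of <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      members <- sample(idx[y == cls])
      fold_of[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  fold_of
}

# Rank-based AUROC (Mann-Whitney), exact under ties via midranks.
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision: sum over recall increments of precision at each
# positive, scanning by decreasing score (ties grouped).
auprc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  if (n1 == 0) return(NA_real_)
  o <- order(-scores)
  lab <- pos[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # evaluate at the last index of each tied score block
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Train a minimal gene-panel probe for a region
#'
#' Binary target: voxel-in-region. For each of `folds` stratified shuffled
#' cross-validation folds, the panel genes are mean-centered and
#' SD-scaled on the training split only, an l2-regularized logistic
#' regression is fit, and held-out AUROC and AUPRC are recorded along with
#' the region's base rate (its fraction of in-mask voxels).
#'
#' @param E Z-scored [expression_matrix()].
#' @param annotation 3D integer label array.
#' @param region Integer region label present in the annotation.
#' @param genes Character vector of panel gene ids (present in `E`).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the shuffled fold assignment.
#' @param lambda Ridge penalty passed to \pkg{glmnet} (default `1/n`, the
#'   common unit-strength l2 default).
#' @return An object of class `probe_panel`: list with `region`,
#'   `gene_ids`, `fold_auroc`, `fold_auprc`, `mean_auroc`, `mean_auprc`,
#'   `pooled_auprc`, `base_rate`, `seed`.
#' @export
train_probe <- function(E, annotation, region, genes, folds = 5L, seed = 1L,
                        lambda = NULL) {
  E <- as_expression_matrix(E)
  folds <- check_count(folds, "folds", min = 2L)
  lab <- labels_at(annotation, E$coords)
  if (!region %in% lab) abort("region not present in the annotation mask")
  y <- as.integer(lab == region)
  if (sum(y) < folds) abort("region has fewer voxels than folds")
  X <- subset_genes(E, genes)$values
  n <- nrow(X)
  lambda <- lambda %||% (1 / n)
  fold_of <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  fold_scores <- purrr::map(seq_len(folds), function(f) {
    tr <- fold_of != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2, sd)
    sdev[sdev < 1e-12] <- 1
    Xs_tr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    Xs_te <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    fit <- glmnet::glmnet(Xs_tr, y[tr], family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    p <- as.numeric(predict(fit, Xs_te, type = "response"))
    list(auroc = auroc(p, y[!tr]), auprc = auprc(p, y[!tr]),
         scores = p, labels = y[!tr])
  })
  fold_auroc <- vapply(fold_scores, `[[`, numeric(1), "auroc")
  fold_auprc <- vapply(fold_scores, `[[`, numeric(1), "auprc")
  pooled <- auprc(unlist(purrr::map(fold_scores, "scores")),
                  unlist(purrr::map(fold_scores, "labels")))
  structure(
    list(region = as.integer(region), gene_ids = genes,
         fold_auroc = fold_auroc, fold_auprc = fold_auprc,
         mean_auroc = mean(fold_auroc), mean_auprc = mean(fold_auprc),
         pooled_auprc = pooled, base_rate = mean(y),
         folds = folds, seed = seed, lambda = lambda),
    class = "probe_panel"
  )
}

#' @export
print.probe_panel <- function(x, ...) {
  cat("<probe_panel> region ", x$region, ", ", length(x$gene_ids),
      " genes, mean AUROC ", signif(x$mean_auroc, 3),
      ", mean AUPRC ", signif(x$mean_auprc, 3),
      " (base rate ", signif(x$base_rate, 3), ")\n", sep = "")
  invisible(x)
}

#' Write a probe panel as JSON
#'
#' @param panel A [train_probe()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_probe_panel <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
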