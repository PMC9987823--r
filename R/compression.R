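#' Rank genes by their contribution across components
#'
#' Aggregates a component set's gene-by-K weight matrix into a single
#' descending gene ranking. The default rule scores each gene by its
#' maximum absolute weight over features, which preserves every feature's
#' top genes; alternatives are the sum of absolute weights and the rank-sum
#' of per-feature absolute-weight ranks. Ties break by gene id order.
#'
#' @param C A [component_set()] with gene weights.
#' @param rule Aggregation rule: `"max"`, `"sum"` or `"ranksum"`.
#' @return Character vector of gene ids, best-ranked first.
#' @export
rank_genes <- function(C, rule = c("max", "sum", "ranksum")) {
  rule <- match.arg(rule)
  if (is.null(C$weights)) {
    abort(paste0("method '", C$method, "' exposes no gene weights"))
  }
  A <- abs(C$weights)
  score <- switch(
    rule,
    max = apply(A, 1, max),
    sum = rowSums(A),
    # higher is better: sum of per-feature ranks of |weight|
    ranksum = rowSums(apply(A, 2, rank))
  )
  C$gene_ids[order(-score, seq_along(score))]
}

#' Iteratively compress the gene set and trace representation fidelity
#'
#' Round 0 fits sparse filtering and K-means on the full matrix — the
#' reference parcellation. Each subsequent round keeps the top-ranked genes
#' (ranking recomputed from the latest fit), refits sparse filtering and
#' K-means on the reduced matrix with the same seed, and records AMI/ARI
#' against the round-0 parcellation and against the annotation. Retained
#' gene sets are nested by construction and the voxel set never changes.
#'
#' @param E Z-scored [expression_matrix()].
#' @param annotation 3D integer label array.
#' @param k_features Number of sparse filtering components (held fixed).
#' @param schedule Strictly decreasing integer vector of gene counts, one
#'   per compression round; `min(schedule) >= k_features`.
#' @param k_clusters Number of K-means clusters (default `k_features`).
#' @param seed Integer seed, reused for every round's fit and clustering.
#' @param max_iter Sparse filtering iteration cap per round.
#' @param n_starts Sparse filtering restarts per round.
#' @param rule Gene ranking rule, see [rank_genes()].
#' @return An object of class `compression_trace`: a tibble with one row
#'   per round (`round`, `n_genes_retained`, `ami_vs_full`, `ari_vs_full`,
#'   `ami_vs_truth`, `ari_vs_truth`, `seed`) carrying the per-round gene
#'   sets as a list column `gene_ids`.
#' @export
compress_iteratively <- function(E, annotation, k_features, schedule,
                                 k_clusters = k_features, seed = 1L,
                                 max_iter = 200L, n_starts = 1L,
                                 rule = "max") {
  E <- as_expression_matrix(E)
  schedule <- vapply(schedule, check_count, integer(1), name = "schedule")
  if (length(schedule) > 1 && any(diff(schedule) >= 0)) {
    abort("`schedule` must be strictly decreasing")
  }
  if (min(schedule) < k_features) {
    abort("min(schedule) must be at least k_features")
  }
  if (max(schedule) > n_genes(E)) {
    abort("schedule entry exceeds the current gene count")
  }
  truth <- labels_at(annotation, E$coords)

  fit_round <- function(Er) {
    C <- sparse_filter(Er, k_features, max_iter = max_iter, seed = seed,
                       n_starts = n_starts)
    p <- kmeans_cluster(C, k_clusters, seed = seed)
    list(C = C, labels = p$labels)
  }

  full <- fit_round(E)
  rows <- list(tibble(
    round = 0L, n_genes_retained = n_genes(E),
    gene_ids = list(E$gene_ids),
    ami_vs_full = 1, ari_vs_full = 1,
    ami_vs_truth = ami(full$labels, truth),
    ari_vs_truth = ari(full$labels, truth),
    seed = seed
  ))

  current_E <- E
  current_fit <- full
  for (r in seq_along(schedule)) {
    keep_n <- schedule[r]
    ranked <- rank_genes(current_fit$C, rule = rule)
    keep <- ranked[seq_len(keep_n)]
    keep <- keep[order(match(keep, current_E$gene_ids))]  # stable column order
    current_E <- subset_genes(current_E, keep)
    current_fit <- fit_round(current_E)
    rows[[r + 1L]] <- tibble(
      round = r, n_genes_retained = keep_n,
      gene_ids = list(keep),
      ami_vs_full = ami(current_fit$labels, full$labels),
      ari_vs_full = ari(current_fit$labels, full$labels),
      ami_vs_truth = ami(current_fit$labels, truth),
      ari_vs_truth = ari(current_fit$labels, truth),
      seed = seed
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("compression_trace", class(out))
  out
}

#' Write a compression trace
#'
#' Scalar columns as CSV; per-round retained gene lists as one-id-per-line
#' text files next to it.
#'
#' @param trace A [compress_iteratively()] result.
#' @param csv_path CSV path.
#' @param gene_list_dir Optional directory for per-round gene lists.
#' @return `csv_path`, invisibly.
#' @export
write_compression_trace <- function(trace, csv_path, gene_list_dir = NULL) {
  readr::write_csv(dplyr::select(trace, -"gene_ids"), csv_path)
  if (!is.null(gene_list_dir)) {
    dir.create(gene_list_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(trace))) {
      writeLines(trace$gene_ids[[i]],
                 file.path(gene_list_dir,
                           sprintf("round_%02d_genes.txt", trace$round[i])))
    }
  }
  invisible(csv_path)
}
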