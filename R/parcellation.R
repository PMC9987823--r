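#' K-means parcellation of component activations
#'
#' Clusters the voxel-by-K feature matrix of a component set into `K`
#' cluster labels with Lloyd's K-means, best of 10 seeded restarts. Labels
#' are 0-based (`0 .. K-1`) and deterministic given the seed.
#'
#' @param C A [component_set()].
#' @param K Number of clusters (>= 1, at most the voxel count).
#' @param seed Integer seed.
#' @param nstart Number of restarts (best inertia kept).
#' @return An object of class `parcellation`: list with `labels` (0-based
#'   integer per voxel), `K`, `inertia`, `seed`, `source` (method of the
#'   component set) and `coords`.
#' @export
kmeans_cluster <- function(C, K, seed = 1L, nstart = 10L) {
  K <- check_count(K, "K")
  X <- C$features
  if (K > nrow(X)) abort("K exceeds the number of voxels")
  km <- withr::with_seed(seed, suppressWarnings(
    kmeans(X, centers = K, nstart = nstart, iter.max = 300L,
           algorithm = "Lloyd")
  ))
  structure(
    list(labels = as.integer(km$cluster) - 1L, K = K,
         inertia = km$tot.withinss, seed = seed,
         source = C$method, coords = C$coords),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> K=", x$K, ", ", length(x$labels),
      " voxels, inertia=", signif(x$inertia, 6), "\n", sep = "")
  invisible(x)
}

contingency <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors differ in length")
  table(factor(a), factor(b))
}

entropy_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

# TRUE when the two labelings are the same partition up to relabeling.
same_partition <- function(ct) {
  all(rowSums(ct > 0) <= 1) && all(colSums(ct > 0) <= 1)
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information adjusted for chance under the permutation
#' (hypergeometric) model, normalized by `max(H(a), H(b))` (max
#' normalization). Identical partitions (up to relabeling) score exactly 1;
#' a constant labeling against anything scores 0 in expectation.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A scalar in (-1, 1].
#' @export
ami <- function(a, b) {
  ct <- contingency(a, b)
  if (same_partition(ct)) return(1)
  N <- sum(ct)
  ai <- rowSums(ct)
  bj <- colSums(ct)
  mi <- mutual_information(ct)
  emi <- expected_mi(ai, bj, N)
  denom <- max(entropy_counts(ai), entropy_counts(bj)) - emi
  if (denom <= .Machine$double.eps) return(0)
  (mi - emi) / denom
}

mutual_information <- function(ct) {
  N <- sum(ct)
  ai <- rowSums(ct)
  bj <- colSums(ct)
  nz <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[nz]
  sum(nij / N * log(N * nij / (ai[nz[, 1]] * bj[nz[, 2]])))
}

# Expected MI under random permutations of one labeling, holding both
# cluster size profiles fixed (hypergeometric model).
expected_mi <- function(ai, bj, N) {
  lgN <- lgamma(N + 1)
  emi <- 0
  for (a_ in ai) {
    for (b_ in bj) {
      lo <- max(1, a_ + b_ - N)
      hi <- min(a_, b_)
      if (hi < lo) next
      nij <- lo:hi
      lw <- lgamma(a_ + 1) + lgamma(b_ + 1) + lgamma(N - a_ + 1) +
        lgamma(N - b_ + 1) - lgN - lgamma(nij + 1) - lgamma(a_ - nij + 1) -
        lgamma(b_ - nij + 1) - lgamma(N - a_ - b_ + nij + 1)
      emi <- emi + sum(exp(lw) * (nij / N) * log(N * nij / (a_ * b_)))
    }
  }
  emi
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement adjusted for chance; identical partitions (up to
#' relabeling) score exactly 1, random agreement scores 0 in expectation.
#'
#' @inheritParams ami
#' @return A scalar in (-1, 1].
#' @export
ari <- function(a, b) {
  ct <- contingency(a, b)
  if (same_partition(ct)) return(1)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(as.numeric(ct)))
  sum_a <- sum(comb2(as.numeric(rowSums(ct))))
  sum_b <- sum(comb2(as.numeric(colSums(ct))))
  total <- comb2(sum(ct))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Sweep the cluster count and score against anatomy
#'
#' Runs [kmeans_cluster()] at every requested `K` and scores the resulting
#' labels against the annotation with [ami()] and [ari()].
#'
#' @param C A [component_set()] (its `coords` locate voxels in the volume).
#' @param annotation 3D integer label array.
#' @param ks Integer vector of cluster counts.
#' @param seed Integer seed (shared across `K` values).
#' @return A tibble of class `sweep_result` with columns `K`, `ami`, `ari`,
#'   `inertia`.
#' @export
sweep_k <- function(C, annotation, ks, seed = 1L) {
  if (!length(ks)) abort("`ks` must be nonempty")
  truth <- labels_at(annotation, C$coords)
  rows <- purrr::map(ks, function(k) {
    p <- kmeans_cluster(C, k, seed = seed)
    tibble(K = as.integer(k), ami = ami(p$labels, truth),
           ari = ari(p$labels, truth), inertia = p$inertia)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Write a parcellation as TSV (and optionally NIfTI)
#'
#' @param p A [kmeans_cluster()] result.
#' @param path TSV path (columns `x`, `y`, `z`, `label`).
#' @param nifti_path Optional NIfTI path; labels are written 1-based with 0
#'   outside the mask.
#' @param dims Grid dimensions, required when `nifti_path` is given.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path, nifti_path = NULL, dims = NULL) {
  readr::write_tsv(dplyr::bind_cols(p$coords, tibble(label = p$labels)), path)
  if (!is.null(nifti_path)) {
    if (is.null(dims)) abort("`dims` is required to write NIfTI")
    vol <- feature_volume(p$labels + 1, p$coords, dims, fill = 0)
    storage.mode(vol) <- "integer"
    write_annotation_nifti(vol, nifti_path)
  }
  invisible(path)
}
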