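#' Dice similarity coefficient of two voxel sets
#'
#' `2|A n B| / (|A| + |B|)`. Sets may be given as logical vectors over the
#' same voxel enumeration (equal length) or as integer index vectors. Two
#' empty sets have no defined overlap and raise an error.
#'
#' @param a,b Logical vectors of equal length, or integer index vectors.
#' @return A scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    if (length(a) != length(b)) abort("logical masks differ in length")
    na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  } else {
    a <- unique(as.integer(a)); b <- unique(as.integer(b))
    na <- length(a); nb <- length(b); ni <- length(intersect(a, b))
  }
  if (na + nb == 0) abort("Dice undefined: both sets empty")
  2 * ni / (na + nb)
}

#' Threshold a feature by exact two-means
#'
#' Splits a scalar per-voxel feature into two clusters with 1-D 2-means,
#' solved exactly: the optimal two clusters are contiguous in sorted order,
#' so the best of the n-1 sorted splits (by within-cluster sum of squares)
#' is the global optimum. Deterministic; invariant to positive rescaling.
#'
#' @param f Finite, non-constant numeric vector.
#' @param seed Ignored (kept for interface symmetry with stochastic
#'   clusterers; the exact solver needs no randomness).
#' @return List with logical masks `low` and `high` (the lower- and
#'   higher-mean clusters); together they partition the voxels.
#' @export
threshold_feature <- function(f, seed = NULL) {
  if (!all(is.finite(f))) abort("non-finite feature values")
  n <- length(f)
  if (n < 2 || max(f) == min(f)) abort("constant feature: 2-means undefined")
  o <- order(f)
  s <- f[o]
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1)
  sse_left <- cs2[k] - cs[k]^2 / k
  sse_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(sse_left + sse_right)  # ties: smallest split index
  low <- logical(n)
  low[o[seq_len(best)]] <- TRUE
  list(low = low, high = !low)
}

#' Match a feature to its best anatomical region
#'
#' Thresholds the feature with [threshold_feature()] and compares both
#' resulting masks against every region of the annotation with [dice()],
#' returning the best (region, mask) combination. Ties are broken in favor
#' of the smaller region id.
#'
#' @param f Per-voxel feature vector (aligned with `coords`).
#' @param annotation 3D integer label array.
#' @param coords Tibble of 0-based voxel coordinates for `f`.
#' @param seed Passed to [threshold_feature()] (unused by the exact solver).
#' @return List with `region` (integer label), `dice` (best score) and
#'   `mask` (the winning logical mask).
#' @export
match_feature_to_regions <- function(f, annotation, coords, seed = NULL) {
  regions <- annotation_labels(annotation)
  if (!length(regions)) abort("annotation has no nonzero region")
  lab <- labels_at(annotation, coords)
  masks <- threshold_feature(f, seed)
  best <- list(region = NA_integer_, dice = -Inf, mask = NULL)
  for (r in regions) {  # ascending ids: strict > keeps the smaller id on ties
    rmask <- lab == r
    if (!any(rmask)) next
    for (m in masks) {
      d <- if (any(m)) dice(m, rmask) else 0
      if (d > best$dice) best <- list(region = r, dice = d, mask = m)
    }
  }
  best
}

#' Feature and weight sparsity ratios
#'
#' The ratio of total elements to "active" elements, where active means
#' strictly greater than the vector mean (signed values as produced by the
#' method). A one-hot vector of length n scores n; the score is always
#' >= 1 when defined. A vector with no element above its mean (i.e. a
#' constant vector) has no active element and raises an error.
#'
#' @param f Per-voxel feature values (`feature_sparsity`) or per-gene
#'   weights (`weight_sparsity`).
#' @return A scalar >= 1.
#' @export
feature_sparsity <- function(f) {
  if (!all(is.finite(f))) abort("non-finite values")
  active <- sum(f > mean(f))
  if (active == 0) abort("no active element: sparsity undefined")
  length(f) / active
}

#' @rdname feature_sparsity
#' @param w Per-gene weight vector.
#' @export
weight_sparsity <- function(w) feature_sparsity(w)

#' Shannon entropy of a binned feature
#'
#' Bins the values into `n_bins` uniform-width bins over `[min, max]` and
#' returns the Shannon entropy (natural log) of the empirical bin
#' probabilities. A constant feature has a single symbol and entropy 0; the
#' value never exceeds `log(n_bins)`. Invariant to affine rescaling of the
#' values (bin edges track the range).
#'
#' @param f Finite numeric vector.
#' @param n_bins Number of bins (>= 1).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(f, n_bins = 256L) {
  n_bins <- check_count(n_bins, "n_bins")
  if (!all(is.finite(f))) abort("non-finite values")
  rng <- range(f)
  if (rng[1] == rng[2]) return(0)
  lev <- pmin(floor((f - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  entropy_counts(tabulate(lev, n_bins))
}

quantize_levels <- function(v, n_levels) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(1L, length(v)))
  pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L, n_levels)
}

#' 3D co-occurrence spatial entropy
#'
#' Gray-level co-occurrence entropy extended to volumes: in-mask voxel
#' values are quantized to `n_levels` uniform levels, co-occurrences of
#' level pairs are accumulated over all in-mask voxel pairs at the given 3D
#' offsets (symmetrized, so both orderings of a pair count), and the
#' Shannon entropy (nats) of the normalized co-occurrence matrix is
#' returned, treating each (i, j) cell as one symbol. A spatially
#' homogeneous volume scores 0; structure lowers the score relative to a
#' value-shuffled volume.
#'
#' @param vol 3D numeric array; `NA` marks out-of-mask voxels (excluded
#'   from all pairs).
#' @param n_levels Number of quantization levels (>= 2).
#' @param offsets Integer matrix, one 3D offset per row (default: the 13
#'   unique nearest-neighbor offsets).
#' @return Entropy in nats.
#' @export
spatial_entropy <- function(vol, n_levels = 16L, offsets = neighbor_offsets_3d()) {
  n_levels <- check_count(n_levels, "n_levels", min = 2L)
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 3 || any(rowSums(abs(offsets)) == 0)) {
    abort("`offsets` must be nonzero integer triples")
  }
  mask <- is.finite(vol)
  if (!any(mask)) abort("empty mask")
  lev <- array(NA_integer_, dim = dim(vol))
  lev[mask] <- quantize_levels(vol[mask], n_levels)
  dims <- dim(vol)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    x1 <- max(1, 1 - off[1]):min(dims[1], dims[1] - off[1])
    y1 <- max(1, 1 - off[2]):min(dims[2], dims[2] - off[2])
    z1 <- max(1, 1 - off[3]):min(dims[3], dims[3] - off[3])
    if (!length(x1) || !length(y1) || !length(z1)) next
    a <- lev[x1, y1, z1, drop = FALSE]
    b <- lev[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * n_levels + b[ok]
    tab <- tabulate(idx, n_levels * n_levels)
    counts <- counts + matrix(tab, n_levels, n_levels, byrow = TRUE)
  }
  counts <- counts + t(counts)  # symmetrize: count both orderings
  if (sum(counts) == 0) abort("no in-mask voxel pair at the given offsets")
  entropy_counts(counts)
}

#' Surface connected components of a thresholded volume
#'
#' Extracts the boundary surface of the above-threshold voxel set (the
#' faces between voxels above and not above the threshold, including grid
#' borders), builds the graph of surface corner vertices connected by face
#' edges, and returns the number of connected components of that graph.
#' For solid blobs separated by at least two voxels this equals the
#' 26-connectivity flood-fill component count.
#'
#' @param vol 3D numeric array (`NA` allowed outside the mask; treated as
#'   below threshold).
#' @param threshold Numeric threshold, or `"mean"` for the mean of the
#'   finite values.
#' @return Integer component count. If no voxel exceeds the threshold a
#'   warning is emitted and 0 is returned.
#' @export
connected_components <- function(vol, threshold = "mean") {
  vals <- vol[is.finite(vol)]
  if (!length(vals)) abort("volume has no finite values")
  thr <- if (identical(threshold, "mean")) mean(vals) else
    check_scalar_number(threshold, "threshold")
  above <- which(is.finite(vol) & vol > thr)
  if (!length(above)) {
    warn("threshold at or above the maximum: no surface extracted")
    return(0L)
  }
  dims <- dim(vol)
  ai <- arrayInd(above, dims)
  inset <- array(FALSE, dims)
  inset[above] <- TRUE
  cd <- dims + 1L  # corner lattice dimensions
  corner_id <- function(x, y, z) (x - 1) + cd[1] * ((y - 1) + cd[2] * (z - 1))
  edges_from <- vector("list", 6L)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  # corner offsets of the 4 vertices of the face in direction `d`, as a
  # cycle (v1-v2-v3-v4): derived per axis
  face_cycle <- function(d) {
    axis <- which(d != 0)
    pos <- d[axis] > 0
    others <- setdiff(1:3, axis)
    base <- matrix(0L, 4, 3)
    base[, axis] <- if (pos) 1L else 0L
    base[, others[1]] <- c(0L, 1L, 1L, 0L)
    base[, others[2]] <- c(0L, 0L, 1L, 1L)
    base
  }
  all_edges <- NULL
  for (f in 1:6) {
    d <- dirs[f, ]
    nx <- ai[, 1] + d[1]; ny <- ai[, 2] + d[2]; nz <- ai[, 3] + d[3]
    inside <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
      nz >= 1 & nz <= dims[3]
    neigh_in <- logical(nrow(ai))
    neigh_in[inside] <- inset[cbind(nx[inside], ny[inside], nz[inside])]
    boundary <- !neigh_in
    if (!any(boundary)) next
    vx <- ai[boundary, 1]; vy <- ai[boundary, 2]; vz <- ai[boundary, 3]
    cyc <- face_cycle(d)
    vid <- sapply(1:4, function(i) {
      corner_id(vx + cyc[i, 1], vy + cyc[i, 2], vz + cyc[i, 3])
    })
    if (is.null(dim(vid))) vid <- matrix(vid, nrow = 1)
    e <- rbind(cbind(vid[, 1], vid[, 2]), cbind(vid[, 2], vid[, 3]),
               cbind(vid[, 3], vid[, 4]), cbind(vid[, 4], vid[, 1]))
    all_edges <- rbind(all_edges, e)
  }
  verts <- unique(as.vector(all_edges))
  g <- igraph::graph_from_edgelist(
    matrix(match(all_edges, verts), ncol = 2), directed = FALSE
  )
  as.integer(igraph::components(g)$no)
}

#' Score every feature of a component set
#'
#' Computes the full per-feature metric suite — best-match region and Dice,
#' surface connected components, feature and weight sparsity, Shannon
#' entropy and 3D co-occurrence spatial entropy — plus aggregates: the
#' number of distinct matched regions and the mean of every metric, and the
#' Pearson correlation between Dice and the connected-components count
#' (reported as-is, for exploration).
#'
#' Per-feature failures (e.g. a constant feature) are recorded as missing
#' values, not raised.
#'
#' @param C A [component_set()].
#' @param annotation 3D integer label array on the grid of `C$coords`.
#' @param n_bins Bins for [shannon_entropy()].
#' @param n_levels Levels for [spatial_entropy()].
#' @param offsets Offsets for [spatial_entropy()].
#' @return An object of class `feature_metric_report`: list with
#'   `per_feature` (tibble, one row per feature) and `aggregates` (list).
#' @export
feature_report <- function(C, annotation, n_bins = 256L, n_levels = 16L,
                           offsets = neighbor_offsets_3d()) {
  K <- n_components(C)
  dims <- dim(annotation)
  rows <- purrr::map(seq_len(K), function(k) {
    f <- C$features[, k]
    vol <- feature_volume(f, C$coords, dims)
    m <- tryCatch(match_feature_to_regions(f, annotation, C$coords),
                  error = function(e) list(region = NA_integer_, dice = NA_real_))
    ncc <- tryCatch(
      suppressWarnings(connected_components(vol, threshold = mean(f))),
      error = function(e) NA_integer_)
    fs <- tryCatch(feature_sparsity(f), error = function(e) NA_real_)
    ws <- if (is.null(C$weights)) NA_real_ else
      tryCatch(weight_sparsity(C$weights[, k]), error = function(e) NA_real_)
    se <- tryCatch(shannon_entropy(f, n_bins), error = function(e) NA_real_)
    spe <- tryCatch(spatial_entropy(vol, n_levels, offsets),
                    error = function(e) NA_real_)
    tibble(
      feature = k, matched_region = m$region, dice = m$dice,
      n_connected_components = ncc, feature_sparsity = fs,
      weight_sparsity = ws, shannon_entropy = se, spatial_entropy = spe
    )
  })
  per_feature <- dplyr::bind_rows(rows)
  ok <- stats::complete.cases(per_feature[, c("dice", "n_connected_components")])
  aggregates <- list(
    unique_region_count = dplyr::n_distinct(
      per_feature$matched_region[!is.na(per_feature$matched_region)]),
    mean_dice = mean(per_feature$dice, na.rm = TRUE),
    mean_connected_components = mean(per_feature$n_connected_components,
                                     na.rm = TRUE),
    mean_feature_sparsity = mean(per_feature$feature_sparsity, na.rm = TRUE),
    mean_weight_sparsity = mean(per_feature$weight_sparsity, na.rm = TRUE),
    mean_shannon_entropy = mean(per_feature$shannon_entropy, na.rm = TRUE),
    mean_spatial_entropy = mean(per_feature$spatial_entropy, na.rm = TRUE),
    cor_dice_components = if (sum(ok) >= 3 &&
                              sd(per_feature$dice[ok]) > 0 &&
                              sd(per_feature$n_connected_components[ok]) > 0)
      cor(per_feature$dice[ok], per_feature$n_connected_components[ok])
    else NA_real_
  )
  structure(list(per_feature = per_feature, aggregates = aggregates),
            class = "feature_metric_report")
}

#' @export
print.feature_metric_report <- function(x, ...) {
  cat("<feature_metric_report> ", nrow(x$per_feature), " features, ",
      x$aggregates$unique_region_count, " unique matched regions, mean Dice ",
      signif(x$aggregates$mean_dice, 3), "\n", sep = "")
  invisible(x)
}

#' Best Dice over all features, per region
#'
#' The complementary view to [feature_report()]: for every annotated region,
#' the best Dice achieved by any feature's thresholded mask, and which
#' feature achieved it.
#'
#' @inheritParams feature_report
#' @return Tibble with columns `region`, `best_dice`, `best_feature`.
#' @export
region_coverage <- function(C, annotation) {
  regions <- annotation_labels(annotation)
  lab <- labels_at(annotation, C$coords)
  K <- n_components(C)
  masks <- purrr::map(seq_len(K), function(k) {
    tryCatch(threshold_feature(C$features[, k]), error = function(e) NULL)
  })
  rows <- purrr::map(regions, function(r) {
    rmask <- lab == r
    best_d <- NA_real_; best_f <- NA_integer_
    for (k in seq_len(K)) {
      if (is.null(masks[[k]])) next
      for (m in masks[[k]]) {
        d <- if (any(m)) dice(m, rmask) else 0
        if (is.na(best_d) || d > best_d) {
          best_d <- d; best_f <- k
        }
      }
    }
    tibble(region = r, best_dice = best_d, best_feature = best_f)
  })
  dplyr::bind_rows(rows)
}

#' Write a feature metric report
#'
#' Per-feature metrics as CSV and aggregates as JSON.
#'
#' @param report A [feature_report()] result.
#' @param csv_path Path for the per-feature CSV.
#' @param json_path Optional path for the aggregate JSON.
#' @return `csv_path`, invisibly.
#' @export
write_feature_report <- function(report, csv_path, json_path = NULL) {
  readr::write_csv(report$per_feature, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(report$aggregates, json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
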