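#' Region geometries for synthetic phantoms
#'
#' Axis-aligned boxes and ellipsoids on the voxel grid, specified in 0-based
#' grid coordinates. Boxes are inclusive of both corners; ellipsoids contain
#' every voxel whose center satisfies the normalized quadratic form.
#'
#' @param label Integer region label (>= 1).
#' @param min,max Integer triples: the two inclusive corners of the box.
#' @param center Numeric triple: ellipsoid center.
#' @param radii Positive numeric triple: ellipsoid semi-axes in voxels.
#' @return A region geometry object used in [phantom_spec()].
#' @export
region_box <- function(label, min, max) {
  label <- check_count(label, "label")
  if (length(min) != 3 || length(max) != 3 || any(max < min)) {
    abort("box needs integer triples `min` <= `max`", class = "voxsparse_geometry_error")
  }
  structure(list(label = label, min = as.integer(min), max = as.integer(max)),
            class = c("region_box", "phantom_region"))
}

#' @rdname region_box
#' @export
region_ellipsoid <- function(label, center, radii) {
  label <- check_count(label, "label")
  if (length(center) != 3 || length(radii) != 3 || any(radii <= 0)) {
    abort("ellipsoid needs a center triple and positive radii",
          class = "voxsparse_geometry_error")
  }
  structure(list(label = label, center = as.numeric(center),
                 radii = as.numeric(radii)),
            class = c("region_ellipsoid", "phantom_region"))
}

region_voxels <- function(region, grid_dims) {
  if (inherits(region, "region_box")) {
    if (any(region$min < 0) || any(region$max > grid_dims - 1L)) {
      abort(paste0("region ", region$label, " exceeds the grid"),
            class = "voxsparse_geometry_error")
    }
    g <- expand.grid(x = region$min[1]:region$max[1],
                     y = region$min[2]:region$max[2],
                     z = region$min[3]:region$max[3])
    return(as.matrix(g))
  }
  c0 <- region$center; r0 <- region$radii
  lo <- pmax(0, floor(c0 - r0)); hi <- pmin(grid_dims - 1L, ceiling(c0 + r0))
  if (any(lo > hi)) {
    abort(paste0("region ", region$label, " contains no voxel"),
          class = "voxsparse_geometry_error")
  }
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  d <- ((g$x - c0[1]) / r0[1])^2 + ((g$y - c0[2]) / r0[2])^2 +
    ((g$z - c0[3]) / r0[3])^2
  inside <- d <= 1
  if (any(g$x[inside] < 0) || any(g$x[inside] > grid_dims[1] - 1L)) {
    abort(paste0("region ", region$label, " exceeds the grid"),
          class = "voxsparse_geometry_error")
  }
  as.matrix(g[inside, , drop = FALSE])
}

#' Specify a synthetic phantom
#'
#' A phantom is a 3D grid carrying disjoint labeled signal regions embedded
#' in a labeled background "tissue" region, plus a gene expression model:
#' each signal region gets `markers_per_region` private marker genes whose
#' raw expression is elevated by `marker_amplitude` inside the region; a
#' fraction `background_fraction` of the remaining genes is uniformly
#' expressed across the whole mask at `background_level`; Gaussian noise of
#' SD `noise_sd` is added everywhere and raw values are floored at zero
#' (expression energies are nonnegative).
#'
#' @param grid_dims Integer triple: voxels per axis.
#' @param regions List of signal region geometries ([region_box()] /
#'   [region_ellipsoid()]) with pairwise distinct labels >= 2 (label 1 is
#'   reserved for the background region). Must be pairwise disjoint.
#' @param n_genes Total number of genes.
#' @param markers_per_region Private marker genes planted per region.
#' @param marker_amplitude Raw signal added inside the region.
#' @param noise_sd SD of additive Gaussian noise (raw units).
#' @param background_fraction Fraction of non-marker genes given uniform
#'   in-mask expression.
#' @param background_level Raw expression level of background genes.
#' @param background Geometry of the mask-filling background region (label
#'   1), or `NULL` for no background (mask = union of signal regions).
#' @param n_shared_markers Number of extra border-style marker genes, each
#'   shared by two adjacent signal regions (0 = all markers private).
#' @param seed Integer seed; all stochastic draws derive from it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_dims, regions, n_genes, markers_per_region,
                         marker_amplitude = 3, noise_sd = 0.5,
                         background_fraction = 0.5, background_level = 1,
                         background = NULL, n_shared_markers = 0L,
                         seed = 1L) {
  grid_dims <- vapply(grid_dims, check_count, integer(1), name = "grid_dims")
  if (length(grid_dims) != 3) abort("`grid_dims` must be a triple")
  n_genes <- check_count(n_genes, "n_genes")
  markers_per_region <- check_count(markers_per_region, "markers_per_region", min = 0L)
  check_scalar_number(marker_amplitude, "marker_amplitude", min = 1e-12)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(background_fraction, "background_fraction", 0, 1)
  check_scalar_number(background_level, "background_level", min = 0)
  n_shared_markers <- check_count(n_shared_markers, "n_shared_markers", min = 0L)
  seed <- check_count(seed, "seed", min = 0L)
  if (!length(regions) || !all(vapply(regions, inherits, logical(1), "phantom_region"))) {
    abort("`regions` must be a non-empty list of region geometries")
  }
  labels <- vapply(regions, `[[`, integer(1), "label")
  if (anyDuplicated(labels) || any(labels < 2L)) {
    abort("signal region labels must be distinct integers >= 2",
          class = "voxsparse_geometry_error")
  }
  total_markers <- markers_per_region * length(regions) + n_shared_markers
  if (total_markers > n_genes) {
    abort("markers_per_region x regions (+ shared) exceeds n_genes")
  }
  spec <- structure(
    list(grid_dims = grid_dims, regions = regions, n_genes = n_genes,
         markers_per_region = markers_per_region,
         marker_amplitude = marker_amplitude, noise_sd = noise_sd,
         background_fraction = background_fraction,
         background_level = background_level, background = background,
         n_shared_markers = n_shared_markers, seed = seed),
    class = "phantom_spec"
  )
  # validate geometry eagerly: in-grid, nonempty, pairwise disjoint
  vox <- lapply(regions, region_voxels, grid_dims = grid_dims)
  if (any(vapply(vox, nrow, integer(1)) == 0L)) {
    abort("every region must contain at least one voxel",
          class = "voxsparse_geometry_error")
  }
  keys <- lapply(vox, function(v) v[, 1] + grid_dims[1] * (v[, 2] + grid_dims[2] * v[, 3]))
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys)) {
    abort("signal regions overlap", class = "voxsparse_geometry_error")
  }
  spec
}

#' The default study phantom
#'
#' Eight 7x7x7 signal regions (labels 2-9) at the corners of the interior of
#' a 20^3 grid, embedded in a 16^3 background box (label 1, about a third of
#' the mask), with 1000 genes, 30 private markers per region, marker
#' amplitude 3, noise SD 0.5 and half of the remaining genes broadly
#' expressed. These are the conditions used by the package's own recovery
#' and compression studies.
#'
#' @param seed Integer master seed.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 1L) {
  lo <- c(2L, 11L)
  regions <- list()
  lab <- 2L
  for (zx in lo) for (zy in lo) for (zz in lo) {
    regions[[length(regions) + 1L]] <-
      region_box(lab, c(zx, zy, zz), c(zx + 6L, zy + 6L, zz + 6L))
    lab <- lab + 1L
  }
  phantom_spec(
    grid_dims = c(20L, 20L, 20L), regions = regions, n_genes = 1000L,
    markers_per_region = 30L, marker_amplitude = 3, noise_sd = 0.5,
    background_fraction = 0.5, background_level = 1,
    background = region_box(1L, c(2L, 2L, 2L), c(17L, 17L, 17L)),
    seed = seed
  )
}

#' A small two-region phantom
#'
#' Two 4x4x4 signal regions (labels 2 and 3) in a 12^3 grid with a
#' mask-filling background, 100 genes and 10 markers per region; handy for
#' examples and fast end-to-end checks.
#'
#' @param seed Integer master seed.
#' @param noise_sd Noise SD (default 0.5).
#' @return A `phantom_spec`.
#' @export
small_phantom_spec <- function(seed = 1L, noise_sd = 0.5) {
  phantom_spec(
    grid_dims = c(12L, 12L, 12L),
    regions = list(region_box(2L, c(1, 1, 1), c(4, 4, 4)),
                   region_box(3L, c(7, 7, 7), c(10, 10, 10))),
    n_genes = 100L, markers_per_region = 10L, marker_amplitude = 3,
    noise_sd = noise_sd, background_fraction = 0.5, background_level = 1,
    background = region_box(1L, c(0, 0, 0), c(11, 11, 11)),
    seed = seed
  )
}

#' Generate a labeled phantom with planted marker genes
#'
#' Builds the annotation volume, the raw voxel-by-gene expression matrix
#' over in-mask voxels, and the per-gene z-scored analysis matrix, together
#' with the ground-truth marker map. Fully deterministic given the spec's
#' seed: two calls with the same spec return identical objects.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements:
#'   * `expression`: z-scored [expression_matrix()] (constant genes dropped),
#'   * `raw`: raw (pre-z-score) `expression_matrix`,
#'   * `annotation`: 3D integer label array (0 outside the mask),
#'   * `markers`: named list, region label -> planted marker gene ids, plus
#'     an optional `shared` element of border marker genes,
#'   * `spec`: the input spec.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec")
  gd <- spec$grid_dims
  vol <- array(0L, dim = gd)
  if (!is.null(spec$background)) {
    bg_vox <- region_voxels(spec$background, gd)
    vol[bg_vox + 1L] <- 1L
  }
  region_vox <- lapply(spec$regions, region_voxels, grid_dims = gd)
  labels <- vapply(spec$regions, `[[`, integer(1), "label")
  for (i in seq_along(spec$regions)) {
    vol[region_vox[[i]] + 1L] <- labels[i]
  }
  coords <- mask_coords(vol)
  M <- nrow(coords)
  if (M == 0L) abort("phantom mask is empty", class = "voxsparse_geometry_error")
  lab_at <- labels_at(vol, coords)

  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  R <- length(labels)
  mpr <- spec$markers_per_region
  out <- withr::with_seed(spec$seed, {
    pool <- sample(gene_ids)  # seeded permutation decides gene roles
    markers <- list()
    used <- 0L
    for (i in seq_len(R)) {
      ids <- sort(pool[used + seq_len(mpr)])
      markers[[as.character(labels[i])]] <- ids
      used <- used + mpr
    }
    shared <- character(0)
    shared_pairs <- NULL
    if (spec$n_shared_markers > 0L) {
      shared <- sort(pool[used + seq_len(spec$n_shared_markers)])
      used <- used + spec$n_shared_markers
      # each shared marker is planted in two distinct regions
      shared_pairs <- replicate(spec$n_shared_markers, sample(R, 2L),
                                simplify = FALSE)
    }
    rest <- if (used > 0L) pool[-seq_len(used)] else pool
    n_bg <- round(length(rest) * spec$background_fraction)
    bg_genes <- sort(utils::head(rest, n_bg))

    X <- matrix(0, nrow = M, ncol = spec$n_genes,
                dimnames = list(NULL, gene_ids))
    if (length(bg_genes)) X[, bg_genes] <- spec$background_level
    for (i in seq_len(R)) {
      in_region <- lab_at == labels[i]
      X[in_region, markers[[as.character(labels[i])]]] <-
        X[in_region, markers[[as.character(labels[i])]]] + spec$marker_amplitude
    }
    if (length(shared)) {
      for (s in seq_along(shared)) {
        for (r in shared_pairs[[s]]) {
          X[lab_at == labels[r], shared[s]] <-
            X[lab_at == labels[r], shared[s]] + spec$marker_amplitude
        }
      }
    }
    if (spec$noise_sd > 0) {
      X <- X + matrix(rnorm(M * spec$n_genes, sd = spec$noise_sd),
                      nrow = M, ncol = spec$n_genes)
    }
    X[X < 0] <- 0  # expression energies are nonnegative
    list(X = X, markers = markers, shared = shared)
  })

  raw <- expression_matrix(out$X, coords, gene_ids)
  expr <- ztransform(raw, quiet = TRUE)
  markers <- out$markers
  if (length(out$shared)) markers$shared <- out$shared
  structure(
    list(expression = expr, raw = raw, annotation = vol,
         markers = markers, spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> grid ", paste(x$spec$grid_dims, collapse = "x"),
      ", ", length(x$spec$regions), " signal regions, ",
      n_voxels(x$expression), " in-mask voxels, ",
      x$spec$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Write phantom artifacts to disk
#'
#' Writes the annotation as NIfTI, the z-scored expression matrix in the
#' TSV dialect, and the marker map as JSON.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation_nifti(phantom$annotation, file.path(dir, "annotation.nii.gz"))
  write_expression_tsv(phantom$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(phantom$markers, file.path(dir, "markers.json"))
  invisible(dir)
}
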