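# The annotation volume is a plain 3D integer array: 0 marks out-of-mask
# voxels, positive integers are region labels (the ground-truth anatomy).

#' Helpers for 3D annotation label volumes
#'
#' An annotation volume is a 3D integer array in which 0 means "outside the
#' mask" and each positive integer labels one region. These helpers extract
#' region ids, in-mask voxel coordinates, and per-voxel labels aligned with
#' the rows of an [expression_matrix()].
#'
#' @param vol 3D integer array of region labels.
#' @param coords Tibble of 0-based voxel coordinates (`x`, `y`, `z`).
#' @return `annotation_labels`: sorted vector of nonzero labels.
#'   `mask_coords`: tibble of 0-based coordinates of all in-mask voxels, in
#'   array storage order. `labels_at`: integer label per coordinate row.
#' @export
annotation_labels <- function(vol) {
  sort(unique(as.integer(vol[vol != 0])))
}

#' @rdname annotation_labels
#' @export
mask_coords <- function(vol) {
  idx <- which(vol != 0)
  ai <- arrayInd(idx, dim(vol))
  tibble(x = ai[, 1] - 1L, y = ai[, 2] - 1L, z = ai[, 3] - 1L)
}

#' @rdname annotation_labels
#' @export
labels_at <- function(vol, coords) {
  idx <- cbind(coords$x + 1L, coords$y + 1L, coords$z + 1L)
  as.integer(vol[idx])
}

# Place a per-voxel vector into a 3D array; positions not covered by coords
# are filled with `fill`.
#' Embed a per-voxel vector into a 3D volume
#'
#' @param f Numeric vector, one value per coordinate row.
#' @param coords Tibble of 0-based voxel coordinates.
#' @param dims Integer triple of grid dimensions.
#' @param fill Value for voxels outside the coordinate set (default `NA`).
#' @return A 3D numeric array.
#' @export
feature_volume <- function(f, coords, dims, fill = NA_real_) {
  if (length(f) != nrow(coords)) abort("`f` and `coords` lengths differ")
  vol <- array(fill, dim = dims)
  idx <- cbind(coords$x + 1L, coords$y + 1L, coords$z + 1L)
  vol[idx] <- f
  vol
}

#' Write / read an annotation volume as NIfTI
#'
#' @param vol 3D integer array of labels.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_annotation_nifti` returns `path` invisibly;
#'   `read_annotation_nifti` returns the 3D integer array.
#' @export
write_annotation_nifti <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "int32"), path)
  invisible(path)
}

#' @rdname write_annotation_nifti
#' @export
read_annotation_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.integer(arr), dim = dim(arr))
}
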