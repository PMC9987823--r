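# Independent oracles used to cross-check package implementations.

# 26-connectivity flood fill on a logical 3D array: the voxel-level
# component-count oracle for the surface-based implementation.
floodfill_components_26 <- function(mask) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  seen <- array(FALSE, dims)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  comp <- 0L
  for (start in idx) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
      lin <- lin[mask[nb] & !seen[nb]]
      if (length(lin)) {
        seen[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  comp
}

# Random volume of solid blobs separated by >= 2 voxels: blobs are placed in
# disjoint 4^3 cells of a 12^3 grid with a 1-voxel margin on each side.
random_blob_volume <- function(seed) {
  withr::with_seed(seed, {
    vol <- array(0, c(12, 12, 12))
    n_cells <- sample(1:5, 1)
    cells <- sample(27, n_cells)
    for (cell in cells) {
      ci <- arrayInd(cell, c(3, 3, 3))
      orig <- (as.integer(ci) - 1L) * 4L + 1L
      sz <- sample(1:2, 3, replace = TRUE)
      off <- vapply(sz, function(s) sample.int(3 - s, 1), integer(1))
      x <- orig[1] + off[1] + seq_len(sz[1]) - 1L
      y <- orig[2] + off[2] + seq_len(sz[2]) - 1L
      z <- orig[3] + off[3] + seq_len(sz[3]) - 1L
      vol[x, y, z] <- 1
    }
    vol
  })
}

# Largest principal angle (radians) between the column spans of two matrices.
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  max(acos(pmin(svd(crossprod(qa, qb))$d, 1)))
}

# Monte-Carlo estimate of AMI: expected MI from random permutations of one
# labeling, plugged into the max-normalized adjustment.
ami_permutation_oracle <- function(a, b, n_perm = 2000, seed = 1) {
  mi <- function(x, y) {
    ct <- table(x, y)
    voxsparse:::mutual_information(ct)
  }
  ha <- voxsparse:::entropy_counts(table(a))
  hb <- voxsparse:::entropy_counts(table(b))
  emi <- withr::with_seed(seed,
    mean(replicate(n_perm, mi(sample(a), b))))
  (mi(a, b) - emi) / (max(ha, hb) - emi)
}
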