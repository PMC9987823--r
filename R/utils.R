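# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a master seed. Kept below 2^31-1
# so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  offsets <- c(
    phantom = 101, fit = 211, parcellate = 307, metrics = 401,
    compress = 503, probe = 601, sweep = 701, folds = 809
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown stage '", stage, "'"))
  }
  as.integer((as.numeric(seed) * 977 + offsets[[stage]]) %% 2147483647)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(paste0("`", name, "` must be a single finite number in [",
                 min, ", ", max, "]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  as.integer(x)
}

# The 13 unique nearest-neighbor 3D offsets (one of each +/- pair), used as
# the default displacement set for the co-occurrence spatial entropy.
neighbor_offsets_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  m <- as.matrix(g[keep, , drop = FALSE])
  dimnames(m) <- NULL
  m
}
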