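# Shared fixtures, cached so expensive fits run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The study phantom: 8 regions, 1000 genes, 20^3 grid (package defaults).
study_phantom <- function() {
  cached("study_phantom", make_phantom(default_phantom_spec(seed = 1)))
}

# Sparse filtering fit of the study phantom at K = 8, study settings.
study_fit <- function() {
  cached("study_fit", sparse_filter(study_phantom()$expression, K = 8,
                                    max_iter = 500, seed = 101, n_starts = 5))
}

# Compression trace down to the 240 planted markers.
study_trace <- function() {
  cached("study_trace", {
    ph <- study_phantom()
    compress_iteratively(ph$expression, ph$annotation, k_features = 8,
                         schedule = c(600L, 360L, 240L), seed = 101,
                         max_iter = 500, n_starts = 5)
  })
}

# Small noiseless two-region phantom for probe and ranking tests.
noiseless_phantom <- function() {
  cached("noiseless_phantom", {
    regions <- list(region_box(2L, c(1, 1, 1), c(4, 4, 4)),
                    region_box(3L, c(7, 7, 7), c(10, 10, 10)))
    make_phantom(phantom_spec(
      c(12L, 12L, 12L), regions, n_genes = 100L, markers_per_region = 10L,
      marker_amplitude = 3, noise_sd = 0, background_fraction = 0.3,
      background = region_box(1L, c(0, 0, 0), c(11, 11, 11)), seed = 5
    ))
  })
}

# Small noisy two-region phantom for cheap end-to-end checks.
small_noisy_phantom <- function() {
  cached("small_noisy_phantom", {
    regions <- list(region_box(2L, c(1, 1, 1), c(4, 4, 4)),
                    region_box(3L, c(7, 7, 7), c(10, 10, 10)))
    make_phantom(phantom_spec(
      c(12L, 12L, 12L), regions, n_genes = 100L, markers_per_region = 10L,
      marker_amplitude = 3, noise_sd = 0.5, background_fraction = 0.5,
      background = region_box(1L, c(0, 0, 0), c(11, 11, 11)), seed = 6
    ))
  })
}

# Mean weight sparsity of dictionary learning across the penalty sweep on
# the study phantom (shared by the adapter and acceptance tests).
study_dlsc_sweep <- function() {
  cached("study_dlsc_sweep", {
    ph <- study_phantom()
    vapply(c(0.1, 1, 10), function(a) {
      C <- decompose(ph$expression, "dlsc", K = 8,
                     hyperparams = list(alpha = a))
      mean(apply(C$weights, 2, function(w)
        tryCatch(weight_sparsity(w), error = function(e) NA_real_)),
        na.rm = TRUE)
    }, numeric(1))
  })
}

# Small pipeline configuration used by determinism / smoke tests.
small_pipeline_config <- function(outdir) {
  merge_config(list(
    seed = 3L, outdir = outdir,
    phantom = list(preset = "small"),
    fit = list(method = "sft", k = 2L, max_iter = 100L, n_starts = 1L),
    parcellate = list(k = 3L, sweep_ks = c(1L, 2L, 3L, 4L)),
    compress = list(schedule = c(60L, 40L), rule = "max"),
    probe = list(n_genes = 5L, folds = 5L)
  ))
}
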