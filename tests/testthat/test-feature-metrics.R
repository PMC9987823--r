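test_that("dice matches the counting formula and is symmetric", {
  expect_equal(dice(c(1, 2, 3), c(2, 3, 4, 5, 6)), 0.5)
  expect_equal(dice(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(dice(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE)), 0)
  expect_error(dice(logical(5), logical(5)), "empty")
  for (s in 1:200) {
    ab <- withr::with_seed(s, list(a = sample(c(TRUE, FALSE), 40, TRUE),
                                   b = sample(c(TRUE, FALSE), 40, TRUE)))
    if (!any(ab$a) && !any(ab$b)) next
    direct <- 2 * sum(ab$a & ab$b) / (sum(ab$a) + sum(ab$b))
    expect_equal(dice(ab$a, ab$b), direct)
    expect_equal(dice(ab$b, ab$a), dice(ab$a, ab$b))
  }
})

test_that("the 1-D two-means threshold is exact and scale-equivariant", {
  m <- threshold_feature(c(0, 0, 0, 10, 10))
  expect_equal(which(m$high), c(4L, 5L))
  expect_equal(which(m$low), 1:3)
  # brute-force oracle: enumerate every sorted split and minimize SSE
  brute_split <- function(f) {
    o <- order(f)
    best_sse <- Inf
    best_k <- NA
    for (k in seq_len(length(f) - 1)) {
      lo <- f[o[1:k]]
      hi <- f[o[(k + 1):length(f)]]
      sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        best_k <- k
      }
    }
    sort(o[seq_len(best_k)])
  }
  for (s in 1:25) {
    f <- withr::with_seed(s, rnorm(30))
    m <- threshold_feature(f)
    expect_equal(which(m$low), brute_split(f))
    expect_true(all(xor(m$low, m$high)))  # exact partition
    m3 <- threshold_feature(3 * f)
    expect_identical(m3$low, m$low)
  }
  expect_error(threshold_feature(rep(2, 10)), "constant")
})

test_that("feature matching recovers indicators and reports bounds", {
  ph <- noiseless_phantom()
  lab <- labels_at(ph$annotation, ph$expression$coords)
  f <- as.numeric(lab == 3) +
    withr::with_seed(1, rnorm(length(lab), sd = 1e-4))
  m <- match_feature_to_regions(f, ph$annotation, ph$expression$coords)
  expect_equal(m$region, 3L)
  expect_gte(m$dice, 0.99)
  expect_error(
    match_feature_to_regions(rep(1, length(lab)), ph$annotation,
                             ph$expression$coords),
    "constant")

  # report on indicator features: one distinct region each
  Fm <- cbind(as.numeric(lab == 1), as.numeric(lab == 2), as.numeric(lab == 3))
  Fm <- Fm + withr::with_seed(2, matrix(rnorm(length(Fm), sd = 1e-4),
                                        nrow = nrow(Fm)))
  C <- component_set(weights = NULL, features = Fm, method = "test",
                     coords = ph$expression$coords)
  rep3 <- feature_report(C, ph$annotation)
  expect_equal(rep3$aggregates$unique_region_count, 3L)
  expect_equal(rep3$per_feature$matched_region, c(1L, 2L, 3L))
  # duplicating a feature column does not add a unique region
  C4 <- component_set(weights = NULL, features = cbind(Fm, Fm[, 3]),
                      method = "test", coords = ph$expression$coords)
  rep4 <- feature_report(C4, ph$annotation)
  expect_equal(rep4$aggregates$unique_region_count, 3L)
})

test_that("sparsity ratios equal direct counts on enumerated vectors", {
  expect_equal(feature_sparsity(c(0, 0, 0, 0, 8)), 5)
  expect_equal(weight_sparsity(c(1, 1, 1, 9)), 4)
  onehot <- c(rep(0, 99), 1)
  expect_equal(feature_sparsity(onehot), 100)
  expect_error(weight_sparsity(rep(3, 10)), "no active")
  # symmetric distributions: about half the mass is above the mean
  for (s in 1:20) {
    f <- withr::with_seed(s, runif(1000))
    expect_gt(feature_sparsity(f), 1.8)
    expect_lt(feature_sparsity(f), 2.2)
  }
})

test_that("shannon entropy hits constructed values and its upper bound", {
  expect_equal(shannon_entropy(rep(4.2, 50)), 0)
  expect_equal(shannon_entropy(c(rep(0, 50), rep(1, 50)), n_bins = 2), log(2))
  for (s in 1:10) {
    f <- withr::with_seed(s, rnorm(500))
    for (nb in c(2, 16, 256)) {
      expect_lte(shannon_entropy(f, nb), log(nb) + 1e-12)
    }
    # affine rescaling leaves the binned distribution unchanged
    expect_equal(shannon_entropy(f, 32), shannon_entropy(5 * f - 3, 32))
  }
})

test_that("spatial entropy scores homogeneity, structure and shuffles", {
  expect_equal(spatial_entropy(array(7, c(5, 5, 5))), 0)
  # two-level checkerboard at a single offset: exactly two symbols
  cb <- array(0, c(6, 6, 6))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) cb[i, j, k] <- (i + j + k) %% 2
  expect_equal(spatial_entropy(cb, n_levels = 4,
                               offsets = matrix(c(1, 0, 0), 1)), log(2))
  # value-shuffled volumes are at least as entropic as the structured one
  ph <- noiseless_phantom()
  f <- ph$expression$values[, ph$markers[["2"]][1]]
  vol <- feature_volume(f, ph$expression$coords, dim(ph$annotation))
  se_structured <- spatial_entropy(vol, n_levels = 8)
  for (s in 1:20) {
    fshuf <- withr::with_seed(s, sample(f))
    vshuf <- feature_volume(fshuf, ph$expression$coords, dim(ph$annotation))
    expect_gte(spatial_entropy(vshuf, n_levels = 8), se_structured)
  }
  # affine invariance (bin edges track the range)
  expect_equal(spatial_entropy(vol, 8), spatial_entropy(2 * vol + 1, 8))
  expect_error(spatial_entropy(array(NA_real_, c(3, 3, 3))), "empty mask")
})

test_that("surface component counts match 26-connectivity flood fill", {
  v <- array(0, c(9, 9, 9))
  v[2:4, 2:4, 2:4] <- 1
  expect_equal(connected_components(v, 0.5), 1L)
  v[6:8, 6:8, 6:8] <- 1
  expect_equal(connected_components(v, 0.5), 2L)
  expect_warning(n0 <- connected_components(array(0, c(5, 5, 5)), 0.5),
                 "no surface")
  expect_equal(n0, 0L)
  for (s in 1:50) {
    vol <- random_blob_volume(s)
    expect_equal(connected_components(vol, 0.5),
                 floodfill_components_26(vol > 0.5))
  }
})

test_that("the metric report survives degenerate features", {
  ph <- noiseless_phantom()
  Fm <- cbind(rep(1, nrow(ph$expression$values)),  # constant: unmatchable
              as.numeric(labels_at(ph$annotation, ph$expression$coords) == 2))
  C <- component_set(weights = cbind(rep(1, 5), c(1, 0, 0, 0, 0)),
                     features = Fm, method = "test",
                     gene_ids = sprintf("g%d", 1:5),
                     coords = ph$expression$coords)
  rep2 <- suppressWarnings(feature_report(C, ph$annotation))
  expect_true(is.na(rep2$per_feature$dice[1]))
  expect_false(is.na(rep2$per_feature$dice[2]))
  expect_equal(rep2$aggregates$unique_region_count, 1L)
})
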