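test_that("phantom generation is deterministic and geometry is exact", {
  spec <- small_phantom_spec(seed = 11)
  ph1 <- make_phantom(spec)
  ph2 <- make_phantom(spec)
  expect_identical(ph1$raw$values, ph2$raw$values)
  expect_identical(ph1$expression$values, ph2$expression$values)
  expect_identical(ph1$annotation, ph2$annotation)

  # voxel count of the matrix equals the nonzero-label voxel count
  expect_equal(nrow(ph1$expression$values), sum(ph1$annotation != 0))
  # region voxel counts recomputed from the annotation match the geometry
  expect_equal(sum(ph1$annotation == 2L), 64L)
  expect_equal(sum(ph1$annotation == 3L), 64L)
  expect_equal(sum(ph1$annotation != 0L), 12L^3)

  # z-scoring postcondition (population convention)
  Z <- ph1$expression$values
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  n <- nrow(Z)
  sds <- sqrt(colMeans(Z^2) - colMeans(Z)^2)
  expect_lt(max(abs(sds - 1)), 1e-9)

  # marker map: disjoint sets of exactly markers_per_region genes
  mk <- ph1$markers[as.character(2:3)]
  expect_equal(lengths(mk), c(`2` = 10L, `3` = 10L))
  expect_length(intersect(mk[[1]], mk[[2]]), 0)
})

test_that("zero-noise markers separate regions in raw expression", {
  ph <- noiseless_phantom()
  raw <- ph$raw$values
  lab <- labels_at(ph$annotation, ph$raw$coords)
  for (r in c(2L, 3L)) {
    for (g in ph$markers[[as.character(r)]]) {
      expect_gt(min(raw[lab == r, g]), max(raw[lab != r, g]))
    }
  }
  # each expressed gene's support is one region or the whole mask
  bf0 <- make_phantom(phantom_spec(
    c(10L, 10L, 10L),
    list(region_box(2L, c(1, 1, 1), c(3, 3, 3)),
         region_box(3L, c(6, 6, 6), c(8, 8, 8))),
    n_genes = 30L, markers_per_region = 5L, marker_amplitude = 2,
    noise_sd = 0, background_fraction = 0,
    background = region_box(1L, c(0, 0, 0), c(9, 9, 9)), seed = 2
  ))
  lab0 <- labels_at(bf0$annotation, bf0$raw$coords)
  for (g in bf0$raw$gene_ids) {
    support <- bf0$raw$values[, g] > 0
    if (!any(support)) next
    expect_true(length(unique(lab0[support])) == 1 || all(support))
  }
})

test_that("the additive noise model yields unit per-gene SD on raw values", {
  # high-baseline background genes: the nonnegativity floor never binds
  spec <- phantom_spec(
    grid_dims = c(20L, 20L, 10L),
    regions = list(region_box(2L, c(0, 0, 0), c(1, 1, 1))),
    n_genes = 200L, markers_per_region = 0L, marker_amplitude = 1,
    noise_sd = 1, background_fraction = 1, background_level = 5,
    background = region_box(1L, c(0, 0, 0), c(19, 19, 9)), seed = 8
  )
  ph <- make_phantom(spec)
  expect_equal(nrow(ph$raw$values), 4000L)
  sds <- apply(ph$raw$values, 2, sd)
  expect_true(all(sds > 0.95 & sds < 1.05))
})

test_that("invalid geometries and marker budgets are rejected", {
  overlapping <- list(region_box(2L, c(1, 1, 1), c(5, 5, 5)),
                      region_box(3L, c(4, 4, 4), c(8, 8, 8)))
  expect_error(
    phantom_spec(c(10L, 10L, 10L), overlapping, n_genes = 50L,
                 markers_per_region = 5L, seed = 1),
    class = "voxsparse_geometry_error"
  )
  expect_error(
    phantom_spec(c(10L, 10L, 10L),
                 list(region_box(2L, c(5, 5, 5), c(12, 6, 6))),
                 n_genes = 50L, markers_per_region = 5L, seed = 1),
    class = "voxsparse_geometry_error"
  )
  expect_error(
    phantom_spec(c(10L, 10L, 10L),
                 list(region_box(2L, c(1, 1, 1), c(3, 3, 3)),
                      region_box(3L, c(6, 6, 6), c(8, 8, 8))),
                 n_genes = 9L, markers_per_region = 5L, seed = 1),
    "exceeds n_genes"
  )
})

test_that("phantom artifacts round-trip through disk formats", {
  ph <- noiseless_phantom()
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  E2 <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(E2$values, ph$expression$values, ignore_attr = TRUE)
  expect_equal(E2$coords, ph$expression$coords)
  ann2 <- read_annotation_nifti(file.path(dir, "annotation.nii.gz"))
  expect_identical(ann2, ph$annotation)
})
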