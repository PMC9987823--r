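fake_components <- function(X) {
  component_set(weights = NULL, features = X, method = "test",
                coords = tibble::tibble(x = seq_len(nrow(X)) - 1L,
                                        y = 0L, z = 0L))
}

test_that("single-cluster and separable two-cloud cases are exact", {
  X <- withr::with_seed(1, rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                                 matrix(rnorm(40, 10, 0.1), 20, 2)))
  C <- fake_components(X)
  p1 <- kmeans_cluster(C, 1, seed = 1)
  expect_length(unique(p1$labels), 1)
  expect_setequal(p1$labels, 0L)
  p2 <- kmeans_cluster(C, 2, seed = 1)
  expect_equal(ami(p2$labels, rep(1:2, each = 20)), 1)
  expect_error(kmeans_cluster(C, 41), "exceeds")
})

test_that("ami and ari score identity, chance and relabeling correctly", {
  a <- rep(1:4, each = 25)
  expect_equal(ami(a, a), 1)
  expect_equal(ari(a, a), 1)
  # relabeled partition is still identical
  b <- c(3, 4, 1, 2)[a]
  expect_equal(ami(a, b), 1)
  expect_equal(ari(a, b), 1)
  # a constant labeling scores ~0 against anything
  for (s in 1:20) {
    r <- withr::with_seed(s, sample(1:4, 100, TRUE))
    expect_lt(abs(ami(rep(1, 100), r)), 0.05)
    expect_lt(abs(ari(rep(1, 100), r)), 0.05)
  }
  # permuting label ids changes nothing
  r <- withr::with_seed(42, sample(1:3, 100, TRUE))
  perm <- c(2, 3, 1)[r]
  expect_equal(ami(a, r), ami(a, perm))
  expect_equal(ari(a, r), ari(a, perm))
  expect_error(ami(1:5, 1:6), "length")
})

test_that("ari matches mclust and ami matches a permutation oracle", {
  skip_if_not_installed("mclust")
  for (s in 1:10) {
    ab <- withr::with_seed(s, list(a = sample(1:4, 80, TRUE),
                                   b = sample(1:3, 80, TRUE)))
    expect_equal(ari(ab$a, ab$b), mclust::adjustedRandIndex(ab$a, ab$b),
                 tolerance = 1e-12)
  }
  ab <- withr::with_seed(3, list(a = sample(1:3, 40, TRUE),
                                 b = sample(1:3, 40, TRUE)))
  expect_lt(abs(ami(ab$a, ab$b) -
                  ami_permutation_oracle(ab$a, ab$b, n_perm = 4000)),
            0.02)
})

test_that("inertia is non-increasing in K and sweeps are reproducible", {
  ph <- small_noisy_phantom()
  C <- sparse_filter(ph$expression, K = 3, max_iter = 80, seed = 2)
  sw1 <- sweep_k(C, ph$annotation, ks = c(1, 2, 3, 4, 6), seed = 5)
  sw2 <- sweep_k(C, ph$annotation, ks = c(1, 2, 3, 4, 6), seed = 5)
  expect_identical(sw1, sw2)
  expect_true(all(diff(sw1$inertia) <= 1e-8))
  # ks = 1 row equals the constant-labeling score by composition
  truth <- labels_at(ph$annotation, C$coords)
  expect_equal(sw1$ami[1], ami(rep(0L, length(truth)), truth))
  expect_error(sweep_k(C, ph$annotation, integer(0)), "nonempty")
})

test_that("parcellations carry 0-based labels and serialize to TSV", {
  ph <- small_noisy_phantom()
  C <- sparse_filter(ph$expression, K = 2, max_iter = 40, seed = 2)
  p <- kmeans_cluster(C, 3, seed = 1)
  expect_setequal(sort(unique(p$labels)), 0:2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(p, path)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(df), length(p$labels))
  expect_named(df, c("x", "y", "z", "label"))
})
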