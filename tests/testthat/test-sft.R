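test_that("the objective matches hand-evaluated normalization chains", {
  # identity activations: both normalizations leave unit vectors
  expect_equal(sft_objective(diag(2)), 2)
  # one feature, positive constants: every example normalizes to 1
  expect_equal(sft_objective(matrix(3, 7, 1)), 7)
  # positive rescaling leaves the objective unchanged
  A <- withr::with_seed(2, matrix(abs(rnorm(30)), 10, 3))
  expect_equal(sft_objective(A), sft_objective(13.7 * A), tolerance = 1e-12)
  # degenerate normalizations raise
  expect_error(sft_objective(cbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("the analytic gradient matches central finite differences", {
  eps <- 1e-8
  dat <- withr::with_seed(7, list(X = matrix(rnorm(24), 6, 4),
                                  W = matrix(rnorm(12), 4, 3)))
  X <- dat$X
  W <- dat$W
  analytic <- voxsparse:::sft_value_grad(W, X, eps = eps)$grad
  # independent oracle: soft-absolute + pure objective, differenced centrally
  f <- function(W) sft_objective(sqrt((X %*% W)^2 + eps))
  h <- 1e-6
  numeric_grad <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wp[i] <- W[i] + h
    Wm <- W; Wm[i] <- W[i] - h
    numeric_grad[i] <- (f(Wp) - f(Wm)) / (2 * h)
  }
  rel_err <- max(abs(numeric_grad - analytic)) / max(abs(analytic))
  expect_lt(rel_err, 1e-4)
})

test_that("fits have a monotone trace and doubly normalized features", {
  ph <- small_noisy_phantom()
  C <- sparse_filter(ph$expression, K = 3, max_iter = 120, seed = 9)
  expect_true(all(diff(C$objective_trace) <= 1e-8))
  row_norms <- sqrt(rowSums(C$features^2))
  expect_lt(max(abs(row_norms - 1)), 1e-9)
  expect_equal(ncol(C$weights), 3)
  expect_equal(nrow(C$features), nrow(ph$expression$values))
})

test_that("fits are bit-identical for a fixed seed", {
  ph <- small_noisy_phantom()
  C1 <- sparse_filter(ph$expression, K = 2, max_iter = 60, seed = 4)
  C2 <- sparse_filter(ph$expression, K = 2, max_iter = 60, seed = 4)
  expect_identical(C1$weights, C2$weights)
  expect_identical(C1$features, C2$features)
  expect_identical(C1$objective_trace, C2$objective_trace)
})

test_that("the objective is invariant to per-feature rescaling of weights", {
  dat <- withr::with_seed(3, list(X = matrix(rnorm(200), 20, 10),
                                  W = matrix(rnorm(40), 10, 4)))
  v1 <- voxsparse:::sft_value_grad(dat$W, dat$X)$value
  W2 <- sweep(dat$W, 2, c(0.1, 3, 42, 0.7), "*")
  v2 <- voxsparse:::sft_value_grad(W2, dat$X)$value
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected before optimization", {
  ph <- small_noisy_phantom()
  expect_error(sparse_filter(ph$expression, K = 10000), "exceeds")
  bad <- ph$expression
  bad$values[1, 1] <- NA
  expect_error(sparse_filter(bad, K = 2), "non-finite")
})

test_that("component sets round-trip through the directory format", {
  ph <- small_noisy_phantom()
  C <- sparse_filter(ph$expression, K = 2, max_iter = 40, seed = 4)
  dir <- withr::local_tempdir()
  write_component_set(C, dir)
  C2 <- read_component_set(dir)
  expect_equal(unname(C2$weights), unname(C$weights), tolerance = 1e-12)
  expect_equal(unname(C2$features), unname(C$features), tolerance = 1e-12)
  expect_identical(C2$method, "sft")
  expect_equal(C2$objective_trace, C$objective_trace, tolerance = 1e-12)
})
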