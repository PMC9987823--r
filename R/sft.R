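# Sparse filtering: learn K components whose doubly-normalized activations
# are l1-sparse. Examples are voxels, input dimensions are genes; the raw
# activation of feature j at voxel i is w_j' x^(i). The soft-absolute
# nonlinearity g(u) = sqrt(u^2 + eps) smooths |u|; each feature (column) is
# l2-normalized across voxels, then each voxel (row) is l2-normalized across
# features, and the objective is the summed l1 norm of the result.

#' Sparse filtering objective of a raw activation matrix
#'
#' Pure function: applies the two normalizations (per feature across
#' examples, then per example across features) to a given activation matrix
#' and returns the summed l1 norm. Used for trace verification and for
#' independent finite-difference gradient checks. Positive rescaling of the
#' input leaves the value unchanged.
#'
#' @param A Numeric matrix of activations, examples (voxels) in rows,
#'   features in columns.
#' @return The scalar objective value.
#' @export
sft_objective <- function(A) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) abort("non-finite activations")
  cn <- sqrt(colSums(A^2))
  if (any(cn == 0)) abort("all-zero feature column: normalization undefined")
  At <- sweep(A, 2, cn, "/")
  rn <- sqrt(rowSums(At^2))
  if (any(rn == 0)) abort("all-zero example row: normalization undefined")
  sum(abs(At / rn))
}

# Objective and analytic gradient with respect to W for input X (M x G).
# Returns list(value, grad (G x K), features (doubly normalized, M x K)).
sft_value_grad <- function(W, X, eps = 1e-8) {
  Z <- X %*% W
  A <- sqrt(Z * Z + eps)
  M <- nrow(A)
  cn <- sqrt(colSums(A * A))
  At <- sweep(A, 2, cn, "/")
  rn <- sqrt(rowSums(At * At))
  Fh <- At / rn
  value <- sum(Fh)
  # backprop through the row normalization (per example):
  s <- rowSums(Fh)
  G2 <- (1 - Fh * s) / rn
  # backprop through the column normalization (per feature):
  d <- colSums(G2 * At)
  G1 <- sweep(G2 - sweep(At, 2, d, "*"), 2, cn, "/")
  dZ <- G1 * (Z / A)
  list(value = value, grad = crossprod(X, dZ), features = Fh)
}

# Limited-memory BFGS with Armijo backtracking. Written in-package so the
# per-iteration objective trace is available; monotone decrease is enforced
# by the line search.
lbfgs_minimize <- function(fg, w0, memory = 10L, max_iter = 300L,
                           gtol = 1e-6) {
  w <- w0
  ev <- fg(w)
  f <- ev$value
  g <- ev$grad
  trace <- f
  S <- list(); Y <- list(); rho <- numeric(0)
  for (iter in seq_len(max_iter)) {
    gnorm <- sqrt(sum(g^2))
    if (gnorm < gtol) break
    # two-loop recursion
    q <- g
    m <- length(S)
    alpha <- numeric(m)
    if (m > 0) {
      for (i in m:1) {
        alpha[i] <- rho[i] * sum(S[[i]] * q)
        q <- q - alpha[i] * Y[[i]]
      }
      gamma <- sum(S[[m]] * Y[[m]]) / sum(Y[[m]] * Y[[m]])
      q <- gamma * q
      for (i in 1:m) {
        beta <- rho[i] * sum(Y[[i]] * q)
        q <- q + (alpha[i] - beta) * S[[i]]
      }
    } else {
      q <- q / gnorm
    }
    p <- -q
    dg <- sum(p * g)
    if (dg >= 0) {  # not a descent direction; fall back to steepest descent
      p <- -g / gnorm
      dg <- sum(p * g)
      S <- list(); Y <- list(); rho <- numeric(0)
    }
    step <- 1
    ok <- FALSE
    for (ls in 1:40) {
      w_new <- w + step * p
      ev_new <- fg(w_new)
      if (is.finite(ev_new$value) && ev_new$value <= f + 1e-4 * step * dg) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) break  # no further decrease achievable
    s_vec <- w_new - w
    y_vec <- ev_new$grad - g
    sy <- sum(s_vec * y_vec)
    if (is.finite(sy) && sy > 1e-10) {
      S <- c(S, list(s_vec)); Y <- c(Y, list(y_vec)); rho <- c(rho, 1 / sy)
      if (length(S) > memory) {
        S <- S[-1]; Y <- Y[-1]; rho <- rho[-1]
      }
    }
    w <- w_new
    f <- ev_new$value
    g <- ev_new$grad
    trace <- c(trace, f)
  }
  list(par = w, value = f, trace = trace, iterations = length(trace) - 1L)
}

#' Fit sparse filtering components
#'
#' Learns a gene-by-K weight matrix whose soft-absolute activations over
#' voxels, after feature-wise and example-wise l2 normalization, have
#' minimal summed l1 norm. Optimized with the package's limited-memory BFGS
#' (memory 10, Armijo backtracking), starting from seeded standard-normal
#' weights; the objective value at every accepted iterate is recorded.
#'
#' @param E An [expression_matrix()] (typically z-scored).
#' @param K Number of components (>= 1, at most the number of voxels).
#' @param max_iter Maximum optimizer iterations.
#' @param seed Integer seed for the weight initialization.
#' @param eps Soft-absolute smoothing constant.
#' @param gtol Gradient-norm stopping tolerance.
#' @param n_starts Number of seeded restarts; the fit with the best final
#'   objective is kept (restart seeds derive deterministically from `seed`).
#' @return A [component_set()] with method `"sft"`; `features` holds the
#'   doubly-normalized activations, `objective_trace` the per-iteration
#'   objective.
#' @export
sparse_filter <- function(E, K, max_iter = 200L, seed = 1L, eps = 1e-8,
                          gtol = 1e-6, n_starts = 1L) {
  E <- as_expression_matrix(E)
  K <- check_count(K, "K")
  max_iter <- check_count(max_iter, "max_iter")
  n_starts <- check_count(n_starts, "n_starts")
  X <- E$values
  if (!all(is.finite(X))) abort("non-finite values in expression matrix")
  if (K > nrow(X)) abort("K exceeds the number of voxels")
  G <- ncol(X)
  fg <- function(W) {
    ev <- sft_value_grad(W, X, eps = eps)
    list(value = ev$value, grad = ev$grad)
  }
  fit <- NULL
  for (s in seq_len(n_starts)) {
    start_seed <- if (s == 1L) seed else derive_seed(seed, "fit") + s
    W0 <- withr::with_seed(start_seed,
                           matrix(rnorm(G * K), nrow = G, ncol = K))
    cand <- lbfgs_minimize(fg, W0, memory = 10L, max_iter = max_iter,
                           gtol = gtol)
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  final <- sft_value_grad(fit$par, X, eps = eps)
  W <- fit$par
  dimnames(W) <- list(E$gene_ids, paste0("f", seq_len(K)))
  Fh <- final$features
  colnames(Fh) <- paste0("f", seq_len(K))
  component_set(
    weights = W, features = Fh, method = "sft",
    hyperparams = list(eps = eps, max_iter = max_iter, gtol = gtol),
    seed = seed, objective_trace = fit$trace,
    gene_ids = E$gene_ids, coords = E$coords
  )
}
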