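#' Learn K components with a comparison method
#'
#' Adapters for the standard decompositions used alongside sparse filtering:
#' PCA (exact SVD), kernel PCA (via \pkg{kernlab}; exposes features only, no
#' gene loadings), FastICA (symmetric fixed point, logcosh contrast), sparse
#' PCA (alternating orthogonal Procrustes / soft-thresholded loadings with
#' l1 penalty `alpha` on the gene loadings) and dictionary learning (genes
#' encoded sparsely over a dictionary of K voxel maps; l1 penalty `alpha` on
#' the per-gene codes). For sparse PCA at `alpha = 0` the learned subspace
#' coincides with PCA.
#'
#' @param E An [expression_matrix()] (typically z-scored).
#' @param method One of `"pca"`, `"kpca"`, `"ica"`, `"spca"`, `"dlsc"` (use
#'   [sparse_filter()] for `"sft"`).
#' @param K Number of components.
#' @param hyperparams Named list: `alpha` (nonnegative; required
#'   conceptually for `spca`/`dlsc`, default 1), `kernel` (one of
#'   `"quadratic"`, `"cubic"`, `"rbf"`, `"sigmoid"`; required for `kpca`),
#'   `max_iter`, `tol`.
#' @param seed Integer seed (ICA rotation initialization; other adapters are
#'   deterministic).
#' @return A [component_set()]. For `kpca` the `weights` field is `NULL`
#'   (kernel methods expose no gene loadings).
#' @export
decompose <- function(E, method, K, hyperparams = list(), seed = 1L) {
  E <- as_expression_matrix(E)
  K <- check_count(K, "K")
  if (K > nrow(E$values)) abort("K exceeds the number of voxels")
  X <- E$values
  if (!all(is.finite(X))) abort("non-finite values in expression matrix")
  hp <- modifyList(list(alpha = 1, kernel = NULL, max_iter = 200L, tol = 1e-7),
                   hyperparams)
  if (!is.null(hp$alpha) && hp$alpha < 0) abort("`alpha` must be nonnegative")
  fit <- switch(
    method,
    pca = fit_pca(X, K),
    kpca = fit_kpca(X, K, hp),
    ica = fit_ica(X, K, seed, hp),
    spca = fit_spca(X, K, hp),
    dlsc = fit_dlsc(X, K, hp),
    abort(paste0("unknown method '", method, "'"))
  )
  W <- fit$weights
  if (!is.null(W)) dimnames(W) <- list(E$gene_ids, paste0("f", seq_len(K)))
  Fm <- fit$features
  colnames(Fm) <- paste0("f", seq_len(K))
  component_set(
    weights = W, features = Fm, method = method,
    hyperparams = fit$hyperparams %||% hp, seed = seed,
    gene_ids = E$gene_ids, coords = E$coords
  )
}

fit_pca <- function(X, K) {
  sv <- svd(X, nu = 0, nv = K)
  V <- sv$v[, seq_len(K), drop = FALSE]
  list(weights = V, features = X %*% V, hyperparams = list())
}

fit_kpca <- function(X, K, hp) {
  kern <- switch(
    hp$kernel %||% abort("`kernel` is required for kpca"),
    quadratic = kernlab::polydot(degree = 2, scale = 1, offset = 1),
    cubic = kernlab::polydot(degree = 3, scale = 1, offset = 1),
    rbf = kernlab::rbfdot(sigma = hp$sigma %||% (1 / ncol(X))),
    sigmoid = kernlab::tanhdot(scale = 1 / ncol(X), offset = 0),
    abort(paste0("unknown kernel '", hp$kernel, "'"))
  )
  kp <- kernlab::kpca(X, kernel = kern, features = K)
  feats <- kernlab::rotated(kp)
  # kernel methods have no gene loadings; recorded explicitly as NULL
  list(weights = NULL, features = feats,
       hyperparams = list(kernel = hp$kernel))
}

# FastICA with symmetric decorrelation and the logcosh contrast. Whitening
# via SVD; gene-side projection vectors are returned as weights so that
# features = X %*% weights.
fit_ica <- function(X, K, seed, hp) {
  M <- nrow(X)
  sv <- svd(X, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  if (any(d < 1e-12)) abort("rank of X is below K; ICA whitening failed")
  Z <- sv$u[, seq_len(K), drop = FALSE] * sqrt(M)  # whitened: cov = I
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), K) %*%
      t(e$vectors) %*% W
  }
  R <- withr::with_seed(seed, matrix(rnorm(K * K), K, K))
  R <- sym_decor(R)
  for (it in seq_len(hp$max_iter)) {
    S <- Z %*% t(R)
    G <- tanh(S)
    Gp <- 1 - G^2
    R_new <- (t(G) %*% Z) / M - diag(colMeans(Gp), K) %*% R
    R_new <- sym_decor(R_new)
    delta <- max(abs(abs(rowSums(R_new * R)) - 1))
    R <- R_new
    if (delta < hp$tol) break
  }
  Wg <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sqrt(M) / d, K) %*% t(R)
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_len(K)) {
    j <- which.max(abs(Wg[, k]))
    if (Wg[j, k] < 0) Wg[, k] <- -Wg[, k]
  }
  list(weights = Wg, features = X %*% Wg, hyperparams = list())
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Sparse PCA: minimize ||X - F W'||_F^2 + 2*alpha*||W||_1 over orthonormal
# voxel factors F and gene loadings W, by alternating an orthogonal
# Procrustes update of F with a soft-threshold update of W. alpha = 0 is a
# fixed point at the SVD solution, so the method degenerates to PCA exactly.
fit_spca <- function(X, K, hp) {
  sv <- svd(X, nu = K, nv = K)
  W <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  for (it in seq_len(hp$max_iter)) {
    XW <- X %*% W
    s2 <- svd(XW, nu = K, nv = K)
    Fm <- s2$u %*% t(s2$v)              # polar factor: orthonormal
    W_new <- soft_threshold(crossprod(X, Fm), hp$alpha)
    if (max(abs(W_new - W)) < hp$tol * (1 + max(abs(W)))) {
      W <- W_new
      break
    }
    W <- W_new
  }
  list(weights = W, features = X %*% W,
       hyperparams = list(alpha = hp$alpha))
}

# Dictionary learning with sparse gene codes: each gene's voxel profile
# (column of X) is approximated as D w_g with a dictionary D of K unit-norm
# voxel maps and an l1 penalty alpha on the code w_g. Coordinate descent on
# the codes, least-squares dictionary update with column renormalization.
fit_dlsc <- function(X, K, hp) {
  M <- nrow(X); G <- ncol(X)
  sv <- svd(X, nu = K, nv = 0)
  D <- sv$u[, seq_len(K), drop = FALSE]  # unit-norm columns
  W <- matrix(0, nrow = G, ncol = K)
  for (it in seq_len(max(10L, hp$max_iter %/% 4L))) {
    # code update: per-gene lasso via coordinate descent (shared Gram)
    Gram <- crossprod(D)                 # K x K, diagonal ~ 1
    B <- crossprod(X, D)                 # G x K
    for (cd in 1:20) {
      W_old <- W
      for (k in seq_len(K)) {
        r_k <- B[, k] - W %*% Gram[, k] + W[, k] * Gram[k, k]
        W[, k] <- soft_threshold(r_k, hp$alpha) / Gram[k, k]
      }
      if (max(abs(W - W_old)) < 1e-8) break
    }
    # dictionary update: ridge-regularized least squares, renormalized
    WtW <- crossprod(W) + diag(1e-10, K)
    D_new <- X %*% W %*% solve(WtW)
    nrm <- sqrt(colSums(D_new^2))
    dead <- nrm < 1e-12
    if (any(dead)) {
      D_new[, dead] <- D[, dead]
      nrm[dead] <- sqrt(colSums(D[, dead, drop = FALSE]^2))
    }
    D_new <- sweep(D_new, 2, nrm, "/")
    if (max(abs(D_new - D)) < hp$tol) {
      D <- D_new
      break
    }
    D <- D_new
  }
  list(weights = W, features = D, hyperparams = list(alpha = hp$alpha))
}
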