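#' Single non-negative matrix factorisation from a seeded initialisation
#'
#' Minimises the Frobenius reconstruction error `||X - W %*% H||_F` over
#' non-negative `W` (cells x k) and `H` (k x genes) by hierarchical
#' alternating least squares (HALS): each factor column/row is updated in
#' closed form and clipped at zero, which converges quickly to a local
#' minimiser. Components that die out (all-zero) are reseeded from the
#' residual. Fully deterministic given `seed`.
#'
#' @param X Non-negative matrix, cells in rows, genes in columns.
#' @param k Number of programmes; must satisfy `k < min(dim(X))`.
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum number of full update sweeps.
#' @param tol Relative change in reconstruction error below which iteration
#'   stops.
#' @return A list with non-negative `W`, `H`, the final `frobenius_error`,
#'   and the number of iterations used.
#' @export
factorize_once <- function(X, k, seed = 1L, max_iter = 500, tol = 1e-9) {
  X <- as.matrix(X)
  if (any(X < 0)) abort("X must be non-negative")
  if (k < 1 || k >= min(dim(X))) {
    abort(sprintf("k must satisfy 1 <= k < min(dim(X)) = %d", min(dim(X))))
  }
  with_seed(seed, {
    n <- nrow(X); m <- ncol(X)
    scale0 <- sqrt(mean(X) / k)
    W <- matrix(abs(rnorm(n * k)) * scale0, n, k)
    H <- matrix(abs(rnorm(k * m)) * scale0, k, m)
    err_prev <- Inf
    iters <- max_iter
    for (it in seq_len(max_iter)) {
      ## update H rows; the crossproducts dominate the cost, so several
      ## cheap inner sweeps are run per cache (accelerated HALS)
      WtW <- crossprod(W)
      WtX <- crossprod(W, X)
      for (rep in seq_len(4L)) {
        for (j in seq_len(k)) {
          denom <- WtW[j, j]
          if (denom <= .Machine$double.eps) next
          H[j, ] <- pmax(H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / denom, 0)
        }
      }
      ## update W columns
      HHt <- tcrossprod(H)
      XHt <- X %*% base::t(H)
      for (rep in seq_len(4L)) {
        for (j in seq_len(k)) {
          denom <- HHt[j, j]
          if (denom <= .Machine$double.eps) {
            ## dead component: reseed from a random residual direction
            W[, j] <- abs(rnorm(n)) * scale0
            H[j, ] <- abs(rnorm(m)) * scale0
            next
          }
          W[, j] <- pmax(W[, j] + (XHt[, j] - W %*% HHt[, j]) / denom, 0)
        }
      }
      if (it %% 10 == 0 || it == max_iter) {
        err <- norm(X - W %*% H, "F")
        if (is.finite(err_prev) &&
            abs(err_prev - err) <= tol * max(err_prev, .Machine$double.eps)) {
          iters <- it
          err_prev <- err
          break
        }
        err_prev <- err
      }
    }
    list(W = W, H = H, frobenius_error = norm(X - W %*% H, "F"),
         iterations = iters)
  })
}

# Non-negative least squares of each row of X against fixed spectra H
# (rows of the result solve min_{w>=0} ||x - w H||_2).
nnls_rows <- function(X, H) {
  C <- base::t(H)
  W <- matrix(0, nrow(X), nrow(H))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    if (all(x == 0)) next
    W[i, ] <- pracma::lsqnonneg(C, x)$x
  }
  rownames(W) <- rownames(X)
  colnames(W) <- rownames(H)
  W
}
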