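test_that("an exactly factorisable matrix is reconstructed to near machine precision", {
  p <- planted_nmf(n = 200, m = 50, k = 3, seed = 42)
  f <- factorize_once(p$X, 3, seed = 7, max_iter = 2000)
  expect_lt(f$frobenius_error, 1e-6 * norm(p$X, "F"))
  expect_true(all(f$W >= 0))
  expect_true(all(f$H >= 0))
})

test_that("factorisation is deterministic given the seed and recovers planted spectra", {
  p <- planted_nmf(n = 200, m = 50, k = 3, seed = 42)
  f1 <- factorize_once(p$X, 3, seed = 7)
  f2 <- factorize_once(p$X, 3, seed = 7)
  expect_identical(f1, f2)
  m <- match_spectra(f1$H, p$H0)
  expect_gte(m$min_cosine, 0.98)
  expect_error(factorize_once(p$X, 60, seed = 1), "k must satisfy")
})

test_that("nearest-neighbour outlier filtering flags exactly the planted noise components", {
  set.seed(31)
  signal <- matrix(rgamma(4 * 30, 2), 4, 30)
  signal <- signal / sqrt(rowSums(signal^2))
  pooled <- signal[rep(1:4, times = 10), ]       # 10 identical restarts
  pooled <- pooled + matrix(rnorm(nrow(pooled) * 30, 0, 1e-4), ncol = 30)
  noise <- matrix(rgamma(3 * 30, 0.5), 3, 30)
  noise <- noise / sqrt(rowSums(noise^2))
  pooled <- rbind(pooled, noise)
  D <- as.matrix(dist(pooled)); diag(D) <- Inf
  nn <- apply(D, 1, min)
  threshold <- (max(nn[1:40]) + min(nn[41:43])) / 2  # between signal and noise
  flagged <- nn > threshold
  expect_identical(unname(which(flagged)), 41:43)
})

test_that("consensus with no outliers reproduces the common solution", {
  p <- planted_nmf(n = 150, m = 45, k = 3, seed = 5)
  cm <- consensus_factorize(p$X, 3, n_restarts = 12, seed = 9)
  expect_s3_class(cm, "gep_model")
  m <- match_spectra(cm$H, p$H0)
  expect_gte(m$min_cosine, 0.98)
  ## with identical-solution restarts nearest-neighbour distances are ~0 and
  ## the default threshold flags at most the allowed 5%
  expect_lte(sum(cm$outlier_mask), ceiling(0.05 * length(cm$outlier_mask)))
  expect_error(consensus_factorize(p$X, 3, n_restarts = 5), "n_restarts")
  expect_error(
    consensus_factorize(p$X, 3, n_restarts = 12,
                        outlier_distance_threshold = -1),
    "relax")
})

test_that("consensus refit usages solve the per-cell NNLS problem (grid oracle)", {
  set.seed(12)
  H <- rbind(c(1, 0.2, 0, 0.1), c(0, 0.1, 1, 0.6))
  X <- matrix(runif(5 * 4, 0, 3), 5, 4)
  W <- gephub:::nnls_rows(X, H)
  grid <- seq(0, 5, by = 0.01)
  for (i in 1:5) {
    obj <- function(w) sum((X[i, ] - w %*% H)^2)
    best <- Inf
    for (w1 in grid) {
      ## profile w2 in closed form given w1, clipped at zero
      resid <- X[i, ] - w1 * H[1, ]
      w2 <- max(0, sum(resid * H[2, ]) / sum(H[2, ]^2))
      best <- min(best, obj(c(w1, w2)))
    }
    expect_lte(obj(W[i, ]), best + 1e-6)
  }
})

test_that("consensus is stable across disjoint restart seed sets", {
  p <- planted_nmf(n = 150, m = 45, k = 3, seed = 5, noise_sd = 0.3)
  a <- consensus_factorize(p$X, 3, n_restarts = 12, seed = 1)
  b <- consensus_factorize(p$X, 3, n_restarts = 12, seed = 1001)
  m <- match_spectra(a$H, b$H)
  expect_gte(m$min_cosine, 0.98)
})

test_that("k selection finds the planted programme count", {
  set.seed(42)
  W0 <- matrix(rgamma(400 * 4, 2), 400, 4)
  H0 <- matrix(0.02, 4, 120)
  for (j in 1:4) H0[j, ((j - 1) * 30 + 1):(j * 30)] <- 1
  rate <- W0 %*% H0
  rate <- rate / rowSums(rate) * 800
  X <- matrix(rpois(length(rate), rate), nrow(rate))
  sel <- select_k(X, 2:6, n_restarts = 10, seed = 5, max_iter = 150)
  expect_equal(sel$k_selected, 4L)
  expect_true(all(diff(sel$diagnostics$frobenius_error) <= 0))
  expect_true(all(sel$diagnostics$silhouette >= -1 &
                    sel$diagnostics$silhouette <= 1))
  m <- match_spectra(sel$model$H, H0)
  expect_gte(m$min_cosine, 0.95)
  expect_error(select_k(X, integer(0)), "non-empty")
  expect_error(select_k(X, 1:3), ">= 2")
})

test_that("gene scores are exact for genes equal to usage columns", {
  set.seed(3)
  W <- matrix(rgamma(300 * 2, 2), 300, 2,
              dimnames = list(NULL, c("gepA", "gepB")))
  X_z <- cbind(W[, 2], rnorm(300), W[, 1] - 2 * W[, 2])
  colnames(X_z) <- c("g1", "g2", "g3")
  B <- gep_gene_scores(X_z, W)
  expect_equal(B[, "g1"], c(gepA = 0, gepB = 1), tolerance = 1e-10)
  expect_equal(B[, "g3"], c(gepA = 1, gepB = -2), tolerance = 1e-10)
})

test_that("gene scores match the normal-equations oracle on a small problem", {
  set.seed(4)
  W <- matrix(rgamma(40 * 2, 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  X_z <- matrix(rnorm(40 * 3), 40, 3,
                dimnames = list(NULL, c("g1", "g2", "g3")))
  B <- gep_gene_scores(X_z, W)
  oracle <- solve(t(W) %*% W) %*% t(W) %*% X_z
  expect_equal(unname(B), unname(oracle), tolerance = 1e-10)
})

test_that("noise genes get vanishing coefficients at large n", {
  set.seed(8)
  W <- matrix(rgamma(2000 * 2, 2), 2000, 2,
              dimnames = list(NULL, c("a", "b")))
  X_z <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "noise"))
  B <- gep_gene_scores(X_z, W)
  expect_true(all(abs(B) < 0.1))
})

test_that("collinear usages are rejected with the offending programmes named", {
  W <- matrix(rgamma(50 * 2, 2), 50, 2)
  W <- cbind(W, W[, 1] * 2)
  colnames(W) <- c("p1", "p2", "p3")
  expect_error(gep_gene_scores(matrix(rnorm(50), 50, 1), W),
               "rank deficient.*p")
})

test_that("top_genes ranks coefficients within each programme", {
  B <- rbind(gepA = c(g1 = 3, g2 = 1, g3 = 2), gepB = c(-1, 5, 0))
  tg <- top_genes(B, n = 2)
  expect_equal(tg$gene[tg$gep_id == "gepA"], c("g1", "g3"))
  expect_equal(tg$gene[tg$gep_id == "gepB"], c("g2", "g3"))
})
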