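#' Consensus non-negative factorisation
#'
#' Runs [factorize_once()] from `n_restarts` seeded initialisations, pools the
#' L2-normalised spectra of all restarts, drops outlying components whose
#' distance to their nearest neighbour exceeds a threshold (by default the
#' 95th percentile of nearest-neighbour distances, a reproducible stand-in
#' for inspecting the distance histogram), clusters the survivors into `k`
#' groups (seeded k-means), takes the per-group median spectrum as the
#' consensus, and refits the usage of every cell against the fixed consensus
#' spectra by non-negative least squares.
#'
#' @param X Non-negative matrix, cells in rows, genes in columns.
#' @param k Number of programmes.
#' @param n_restarts Number of seeded restarts (>= 10).
#' @param outlier_distance_threshold Distance above which a pooled component
#'   is discarded; `NULL` uses the 95th percentile of nearest-neighbour
#'   distances.
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param prefix Prefix for programme ids (e.g. `"pM"` gives `pM01`, `pM02`,
#'   ...).
#' @param max_iter,tol Passed to [factorize_once()].
#' @return A `gep_model` object: consensus `H` (k x genes, rows L2-normalised),
#'   refit `W` (cells x k), mean `silhouette` of the pooled spectra against
#'   their consensus clusters, `frobenius_error` of the refit, the logical
#'   `outlier_mask` over pooled restart components, and bookkeeping fields.
#' @export
consensus_factorize <- function(X, k, n_restarts = 30,
                                outlier_distance_threshold = NULL,
                                seed = 1L, prefix = "gep",
                                max_iter = 500, tol = 1e-9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- sprintf("cell%d", seq_len(nrow(X)))
  if (n_restarts < 10) abort("n_restarts must be >= 10")
  if (k < 2) abort("k must be >= 2 (component clustering is undefined at k = 1)")
  runs <- lapply(seq_len(n_restarts) - 1L, function(r) {
    factorize_once(X, k, seed = seed + r, max_iter = max_iter, tol = tol)
  })
  pooled <- do.call(rbind, lapply(runs, function(z) {
    z$H / pmax(sqrt(rowSums(z$H^2)), .Machine$double.eps)
  }))

  D <- as.matrix(stats::dist(pooled))
  diag(D) <- Inf
  nn_dist <- apply(D, 1, min)
  threshold <- outlier_distance_threshold %||%
    unname(quantile(nn_dist, 0.95, type = 7))
  outlier_mask <- nn_dist > threshold
  survivors <- pooled[!outlier_mask, , drop = FALSE]
  if (nrow(survivors) < k) {
    abort(paste("outlier filtering left fewer components than clusters;",
                "relax outlier_distance_threshold"))
  }

  km <- with_seed(seed, stats::kmeans(survivors, centers = k, nstart = 10,
                                      iter.max = 100))
  if (any(tabulate(km$cluster, k) == 0)) {
    abort(paste("a consensus cluster is empty after outlier filtering;",
                "relax outlier_distance_threshold"))
  }
  sil <- cluster::silhouette(km$cluster, stats::dist(survivors))
  silhouette <- mean(sil[, "sil_width"])

  H <- base::t(vapply(seq_len(k), function(cl) {
    apply(survivors[km$cluster == cl, , drop = FALSE], 2, median)
  }, numeric(ncol(X))))
  H <- H / pmax(sqrt(rowSums(H^2)), .Machine$double.eps)
  ## deterministic programme order: by decreasing cluster size, ties by first
  ## occurrence
  ord <- order(-tabulate(km$cluster, k), seq_len(k))
  H <- H[ord, , drop = FALSE]
  rownames(H) <- sprintf("%s%02d", prefix, seq_len(k))
  colnames(H) <- colnames(X)

  W <- nnls_rows(X, H)
  structure(list(
    k = k,
    H = H,
    W = W,
    silhouette = silhouette,
    frobenius_error = norm(X - W %*% H, "F"),
    outlier_mask = outlier_mask,
    outlier_threshold = threshold,
    nn_distances = nn_dist,
    solver = "hals",
    n_restarts = n_restarts,
    seed = seed
  ), class = "gep_model")
}

#' @export
print.gep_model <- function(x, ...) {
  cat(sprintf(paste0("<gep_model> k = %d (%d cells x %d genes); ",
                     "silhouette %.3f, Frobenius error %.3g, ",
                     "%d/%d outlier components\n"),
              x$k, nrow(x$W), ncol(x$H), x$silhouette, x$frobenius_error,
              sum(x$outlier_mask), length(x$outlier_mask)))
  invisible(x)
}

#' Select the number of programmes
#'
#' Runs [consensus_factorize()] across a range of `k` and reports the mean
#' silhouette of pooled restart spectra against their consensus clusters and
#' the Frobenius reconstruction error for each. Selection uses both criteria:
#' every `k` whose silhouette is within `silhouette_tol` of the maximum is
#' considered equally stable (a consensus of restarts is equally tight for
#' every `k` at or below the true programme count, so exact argmax would
#' ignore the error criterion entirely), and among those the smallest
#' reconstruction error wins, with remaining ties broken by smaller `k`.
#' Biological interpretability of the top-weighted genes is not automated:
#' the diagnostics table is returned for human review.
#'
#' @param X Non-negative matrix, cells in rows, genes in columns.
#' @param k_range Integer vector of candidate `k` values (all >= 2).
#' @param n_restarts Restarts per candidate.
#' @param seed Integer seed.
#' @param silhouette_tol Stability tolerance: candidates within this much of
#'   the best silhouette are ranked by reconstruction error (default 0.02).
#' @param ... Passed to [consensus_factorize()].
#' @return A list with `k_selected`, a `diagnostics` tibble
#'   (`k`, `silhouette`, `frobenius_error`, `n_outliers`), and `model`, the
#'   fitted `gep_model` at `k_selected`.
#' @export
select_k <- function(X, k_range, n_restarts = 15, seed = 1L,
                     silhouette_tol = 0.02, ...) {
  if (length(k_range) == 0) abort("k_range must be non-empty")
  if (any(k_range < 2)) abort("k must be >= 2 (silhouette undefined at k = 1)")
  models <- lapply(k_range, function(k) {
    consensus_factorize(X, k, n_restarts = n_restarts, seed = seed, ...)
  })
  diagnostics <- tibble(
    k = as.integer(k_range),
    silhouette = vapply(models, `[[`, numeric(1), "silhouette"),
    frobenius_error = vapply(models, `[[`, numeric(1), "frobenius_error"),
    n_outliers = vapply(models, function(m) sum(m$outlier_mask), integer(1))
  )
  stable <- diagnostics |>
    filter(.data$silhouette >= max(.data$silhouette) - silhouette_tol) |>
    arrange(.data$frobenius_error, .data$k)
  k_selected <- stable$k[[1]]
  list(k_selected = k_selected,
       diagnostics = diagnostics,
       model = models[[match(k_selected, k_range)]])
}

#' Gene scores for each programme
#'
#' Regresses the z-scored expression of every gene jointly on all consensus
#' usage columns (multiple least squares, no intercept) and returns the
#' k x genes coefficient matrix. Ranking a programme's coefficients gives its
#' top-weighted gene list.
#'
#' @param X_z Cells x genes matrix of z-scored expression (see
#'   [zscore_genes()]).
#' @param W_consensus Cells x k usage matrix of full column rank.
#' @return A k x genes coefficient matrix with the dimnames of
#'   `W_consensus`/`X_z`.
#' @export
gep_gene_scores <- function(X_z, W_consensus) {
  X_z <- as.matrix(X_z)
  W <- as.matrix(W_consensus)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    dep <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]] %||%
      qrW$pivot[(qrW$rank + 1):ncol(W)]
    abort(paste0("usage matrix is rank deficient; collinear GEPs: ",
                 paste(dep, collapse = ", ")))
  }
  B <- solve(crossprod(W), crossprod(W, X_z))
  rownames(B) <- colnames(W)
  colnames(B) <- colnames(X_z)
  B
}

#' Top-weighted genes per programme
#'
#' @param gene_scores Coefficient matrix from [gep_gene_scores()].
#' @param n Number of genes per programme (150 for enrichment-style use, 50
#'   for shared-gene displays).
#' @return A tibble with `gep_id`, `gene`, `score`, `rank`.
#' @export
top_genes <- function(gene_scores, n = 150) {
  purrr::map_dfr(rownames(gene_scores), function(g) {
    sc <- sort(gene_scores[g, ], decreasing = TRUE)
    tibble(gep_id = g, gene = names(sc)[seq_len(min(n, length(sc)))],
           score = unname(sc[seq_len(min(n, length(sc)))]),
           rank = seq_len(min(n, length(sc))))
  })
}
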