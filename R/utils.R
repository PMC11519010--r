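# Small numeric utilities shared across modules.

# Type-7 (linear interpolation) empirical quantile, the convention used for
# per-sample activity summaries. Accepts unsorted input.
quantile7 <- function(x, probs) {
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, length(probs)))
  if (n == 1L) return(rep(x[[1L]], length(probs)))
  xs <- sort.int(x, method = "quick")
  h <- (n - 1) * probs
  lo <- floor(h)
  frac <- h - lo
  lo <- pmin(lo, n - 1)
  xs[lo + 1L] * (1 - frac) + xs[pmin(lo + 2L, n)] * frac
}

# Row-wise cosine similarity between two matrices with matching columns.
cosine_rows <- function(A, B) {
  An <- A / pmax(sqrt(rowSums(A^2)), .Machine$double.eps)
  Bn <- B / pmax(sqrt(rowSums(B^2)), .Machine$double.eps)
  An %*% base::t(Bn)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Match estimated spectra to reference spectra
#'
#' Finds the one-to-one assignment of estimated programme spectra to reference
#' spectra that maximises total cosine similarity. The assignment is solved
#' exactly by exhaustive enumeration for up to eight programmes (all uses in
#' this package) and greedily beyond that.
#'
#' @param H_est,H_ref Matrices with programmes in rows and genes in columns;
#'   equal column counts, equal row counts.
#' @return A list with `perm` (index into `H_ref` rows for each `H_est` row),
#'   `cosines` (matched per-programme cosine similarities), and `min_cosine`.
#' @export
match_spectra <- function(H_est, H_ref) {
  stopifnot(nrow(H_est) == nrow(H_ref), ncol(H_est) == ncol(H_ref))
  k <- nrow(H_est)
  S <- cosine_rows(H_est, H_ref)
  if (k <= 8L) {
    perms <- all_permutations(k)
    best <- NULL
    best_val <- -Inf
    for (p in perms) {
      v <- sum(S[cbind(seq_len(k), p)])
      if (v > best_val) {
        best_val <- v
        best <- p
      }
    }
    perm <- best
  } else {
    perm <- integer(k)
    free <- rep(TRUE, k)
    for (i in order(apply(S, 1, max), decreasing = TRUE)) {
      j <- which.max(ifelse(free, S[i, ], -Inf))
      perm[i] <- j
      free[j] <- FALSE
    }
  }
  cosines <- S[cbind(seq_len(k), perm)]
  list(perm = perm, cosines = cosines, min_cosine = min(cosines))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' quantify recovery of planted hub structure.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# z-score columns (genes) of a dense expression matrix; zero-variance genes
# error because downstream regression coefficients would be undefined.
#' Z-score genes across cells
#'
#' Centres and scales each gene (column) to mean 0 and unit standard deviation,
#' the normalisation expected by [gep_gene_scores()].
#'
#' @param X Dense numeric matrix, cells in rows, genes in columns.
#' @return A matrix of the same shape.
#' @export
zscore_genes <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0)) {
    abort(paste0("zero-variance genes cannot be z-scored: ",
                 paste(head(colnames(X)[sdv == 0], 5), collapse = ", ")))
  }
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}
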