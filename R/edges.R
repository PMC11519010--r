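# Pairwise covariation statistics between programmes: per-quantile Pearson
# correlations across samples, Fisher-transformed and averaged, tested
# against a stratified permutation null.

FISHER_CLIP <- 1 - 1e-7

fisher_z <- function(r) atanh(pmin(pmax(r, -FISHER_CLIP), FISHER_CLIP))

#' Covariation statistic for one programme pair
#'
#' Pearson correlation of the two programmes' per-sample activities at each
#' quantile, Fisher-transformed and averaged into a single test statistic.
#' Quantiles at which either activity vector has zero variance are excluded
#' from the mean (with a note).
#'
#' @param activity Long activity tibble from [activity_quantiles()].
#' @param gep_i,gep_j Programme ids.
#' @param samples Optional sample ids to restrict to; default all samples with
#'   non-missing activity for both programmes (at least 3 required).
#' @return A list with `r_per_quantile` (named numeric), `z_mean`,
#'   `n_samples`, and `dropped_quantiles`.
#' @export
edge_statistic <- function(activity, gep_i, gep_j, samples = NULL) {
  probs <- attr(activity, "quantiles") %||% sort(unique(activity$quantile))
  ai <- activity |> filter(.data$gep_id == gep_i)
  aj <- activity |> filter(.data$gep_id == gep_j)
  if (nrow(ai) == 0 || nrow(aj) == 0) abort("unknown programme id")
  wide_i <- tidyr::pivot_wider(ai, id_cols = "sample_id",
                               names_from = "quantile",
                               values_from = "activity")
  wide_j <- tidyr::pivot_wider(aj, id_cols = "sample_id",
                               names_from = "quantile",
                               values_from = "activity")
  shared <- dplyr::inner_join(wide_i, wide_j, by = "sample_id",
                              suffix = c("_i", "_j"))
  if (!is.null(samples)) shared <- shared |> filter(.data$sample_id %in% samples)
  shared <- shared[complete.cases(shared), , drop = FALSE]
  if (nrow(shared) < 3) {
    abort("at least 3 shared samples with non-missing activity are required")
  }
  r <- vapply(probs, function(q) {
    x <- shared[[paste0(q, "_i")]]
    y <- shared[[paste0(q, "_j")]]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  names(r) <- probs
  dropped <- probs[is.na(r)]
  if (length(dropped) > 0) {
    inform(sprintf("edge_statistic: %d zero-variance quantile(s) excluded",
                   length(dropped)))
  }
  list(r_per_quantile = r,
       z_mean = mean(fisher_z(r), na.rm = TRUE),
       n_samples = nrow(shared),
       dropped_quantiles = dropped)
}

# Correlation of activity columns at one quantile slice; returns the values
# for the requested pairs, NA where variance vanishes.
pair_cor_slice <- function(Aq, idx_i, idx_j) {
  suppressWarnings(C <- cor(Aq, use = "pairwise.complete.obs"))
  C[cbind(idx_i, idx_j)]
}

#' Permutation test for programme covariation
#'
#' For every programme pair, compares the observed mean Fisher-transformed
#' per-quantile correlation with a null distribution obtained by shuffling
#' the cells' sample identities within each compartment stratum `n_perm`
#' times and recomputing the quantile activities and the statistic. The
#' two-sided p-value is twice the smaller of the counts of permuted
#' statistics at or above / at or below the observed one, divided by the
#' number of permutations, floored at `2 / n_perm`. The adjusted correlation
#' is the difference between the mean observed and mean permuted correlation,
#' on the correlation scale.
#'
#' @param W Cells x programmes usage matrix (cell ids as row names).
#' @param cell_meta Tibble with `cell_id`, `sample_id`, `compartment` per row
#'   of `W`.
#' @param gep_info Tibble mapping `gep_id` to `compartment`; `NULL` treats all
#'   cells as one stratum.
#' @param gep_pairs Optional two-column matrix/data frame of programme id
#'   pairs to test; default all pairs.
#' @param quantiles Quantile grid (default 0.25, 0.5, 0.75, 0.95, 0.99).
#' @param n_perm Number of permutations (>= 100; the study-scale default is
#'   10,000).
#' @param seed Integer seed.
#' @param samples Optional sample ids to restrict to (e.g. inflamed samples
#'   only).
#' @param min_shared Minimum shared samples for a pair to be testable
#'   (default 3).
#' @return A tibble with one row per pair: `gep_i`, `gep_j`, `n_samples`,
#'   `r_per_quantile` (list column), `r_true_mean`, `z_mean_true`,
#'   `z_mean_perm`, `r_perm_mean`, `r_adjusted`, `p_value`, `untestable`.
#' @export
permutation_null <- function(W, cell_meta, gep_info = NULL, gep_pairs = NULL,
                             quantiles = DEFAULT_QUANTILES,
                             n_perm = 10000, seed = 1L, samples = NULL,
                             min_shared = 3) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == nrow(cell_meta))
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (!is.null(samples)) {
    keep <- cell_meta$sample_id %in% samples
    W <- W[keep, , drop = FALSE]
    cell_meta <- cell_meta[keep, , drop = FALSE]
  }
  sample_levels <- sort(unique(cell_meta$sample_id))
  strata <- build_strata(W, cell_meta, gep_info)

  ## strata with < 2 samples cannot be permuted meaningfully; their GEPs are
  ## untestable
  untestable_geps <- character(0)
  for (st in strata) {
    if (length(unique(st$labels)) < 2) {
      untestable_geps <- c(untestable_geps, colnames(W)[st$gep_cols])
    }
  }

  if (is.null(gep_pairs)) {
    gep_pairs <- base::t(combn(colnames(W), 2))
  }
  gep_pairs <- as.matrix(gep_pairs)
  idx_i <- match(gep_pairs[, 1], colnames(W))
  idx_j <- match(gep_pairs[, 2], colnames(W))
  if (anyNA(idx_i) || anyNA(idx_j)) abort("unknown programme id in gep_pairs")
  n_pairs <- nrow(gep_pairs)
  nq <- length(quantiles)

  true_act <- compute_activity_array(W, strata, sample_levels, quantiles)
  r_true <- matrix(NA_real_, n_pairs, nq)
  for (qi in seq_len(nq)) {
    r_true[, qi] <- pair_cor_slice(true_act$A[, , qi], idx_i, idx_j)
  }
  z_true <- rowMeans(fisher_z(r_true), na.rm = TRUE)
  r_true_mean <- rowMeans(r_true, na.rm = TRUE)

  present <- !is.na(true_act$A[, , 1])
  n_shared <- vapply(seq_len(n_pairs), function(p) {
    sum(present[, idx_i[p]] & present[, idx_j[p]])
  }, numeric(1))

  count_above <- integer(n_pairs)
  count_below <- integer(n_pairs)
  n_valid <- integer(n_pairs)
  sum_z_perm <- numeric(n_pairs)
  sum_r_perm <- numeric(n_pairs)
  r_perm_q <- matrix(NA_real_, n_pairs, nq)

  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_labels <- lapply(strata, function(st) {
        st$labels[sample.int(length(st$labels))]
      })
      act <- compute_activity_array(W, strata, sample_levels, quantiles,
                                    perm_labels = perm_labels)
      for (qi in seq_len(nq)) {
        r_perm_q[, qi] <- pair_cor_slice(act$A[, , qi], idx_i, idx_j)
      }
      z_perm <- rowMeans(fisher_z(r_perm_q), na.rm = TRUE)
      r_perm <- rowMeans(r_perm_q, na.rm = TRUE)
      ok <- !is.na(z_perm) & !is.na(z_true)
      count_above[ok] <- count_above[ok] + (z_perm[ok] >= z_true[ok])
      count_below[ok] <- count_below[ok] + (z_perm[ok] <= z_true[ok])
      n_valid[ok] <- n_valid[ok] + 1L
      sum_z_perm[ok] <- sum_z_perm[ok] + z_perm[ok]
      sum_r_perm[ok] <- sum_r_perm[ok] + r_perm[ok]
    }
  })

  untestable <- gep_pairs[, 1] %in% untestable_geps |
    gep_pairs[, 2] %in% untestable_geps |
    n_shared < min_shared | n_valid == 0
  p_value <- rep(NA_real_, n_pairs)
  ok <- !untestable
  p_value[ok] <- pmin(1, pmax(2 * pmin(count_above[ok], count_below[ok]), 2) /
                        n_valid[ok])
  tibble(
    gep_i = gep_pairs[, 1],
    gep_j = gep_pairs[, 2],
    n_samples = as.integer(n_shared),
    r_per_quantile = lapply(seq_len(n_pairs), function(p) {
      setNames(r_true[p, ], quantiles)
    }),
    r_true_mean = r_true_mean,
    z_mean_true = z_true,
    z_mean_perm = ifelse(n_valid > 0, sum_z_perm / n_valid, NA_real_),
    r_perm_mean = ifelse(n_valid > 0, sum_r_perm / n_valid, NA_real_),
    r_adjusted = r_true_mean -
      ifelse(n_valid > 0, sum_r_perm / n_valid, NA_real_),
    p_value = p_value,
    untestable = untestable
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement, and
#' the significance mask at the requested FDR.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param fdr Target false discovery rate (default 0.10).
#' @return A list with `p_adjusted` and logical `significant`
#'   (`p_adjusted <= fdr`). Empty input yields empty output.
#' @export
bh_adjust <- function(p_values, fdr = 0.10) {
  if (length(p_values) == 0) {
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  }
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= fdr)
}

#' Adjust a table of edge statistics
#'
#' Applies [bh_adjust()] to the testable edges of a [permutation_null()]
#' result (one family across all tested pairs).
#'
#' @param edges Tibble from [permutation_null()].
#' @param fdr Target FDR (default 0.10).
#' @return The tibble with `p_adjusted` and `significant` columns added.
#' @export
adjust_edge_stats <- function(edges, fdr = 0.10) {
  edges$p_adjusted <- NA_real_
  edges$significant <- FALSE
  ok <- !edges$untestable & !is.na(edges$p_value)
  if (any(ok)) {
    adj <- bh_adjust(edges$p_value[ok], fdr = fdr)
    edges$p_adjusted[ok] <- adj$p_adjusted
    edges$significant[ok] <- adj$significant
  }
  edges
}
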