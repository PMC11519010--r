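#' Project fixed programme spectra onto external expression profiles
#'
#' Intersects the genes of the spectra matrix and the expression matrix, then
#' solves, for every sample, the non-negative least squares problem
#' `min_{w >= 0} ||x - w H||_2` with the spectra held strictly fixed (the
#' reference programmes are never altered; this is projection, not
#' re-factorisation). Negative expression entries are clamped to zero with a
#' logged count. The operation is scale-agnostic: the input normalisation
#' (RPKM, Q3, TP10K pseudobulk, ...) is recorded, not changed.
#'
#' @param H Non-negative spectra matrix, programmes in rows, gene names as
#'   column names.
#' @param X_bulk Samples x genes expression matrix with gene names as column
#'   names.
#' @param renormalize If `TRUE`, scale each sample's projected usages to sum
#'   to one.
#' @param scale_label Free-text record of the expression scale of `X_bulk`.
#' @return A `gep_projection` object: tibble with `sample_id`, one usage
#'   column per programme, and `residual_norm`; attributes `genes_used`,
#'   `genes_dropped` (count not shared), `n_clamped`, `scale_label`, and the
#'   usage matrix `W` itself.
#' @export
project_geps <- function(H, X_bulk, renormalize = FALSE,
                         scale_label = "as-provided") {
  H <- as.matrix(H)
  X <- as.matrix(X_bulk)
  if (any(H < 0)) abort("H must be non-negative")
  shared <- intersect(colnames(H), colnames(X))
  if (length(shared) < nrow(H)) {
    abort(sprintf("only %d shared genes for %d programmes; projection underdetermined",
                  length(shared), nrow(H)))
  }
  genes_dropped <- ncol(X) - length(shared)
  Hs <- H[, shared, drop = FALSE]
  Xs <- X[, shared, drop = FALSE]
  n_clamped <- sum(Xs < 0)
  if (n_clamped > 0) {
    inform(sprintf("project_geps: clamped %d negative entries to zero",
                   n_clamped))
    Xs[Xs < 0] <- 0
  }
  zero_rows <- rowSums(Xs) == 0
  if (any(zero_rows)) {
    warn(sprintf("project_geps: %d all-zero sample(s) get zero usages",
                 sum(zero_rows)))
  }
  W <- nnls_rows(Xs, Hs)
  residual <- sqrt(rowSums((Xs - W %*% Hs)^2))
  if (renormalize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  sample_ids <- rownames(X) %||% sprintf("sample%03d", seq_len(nrow(X)))
  out <- dplyr::bind_cols(
    tibble(sample_id = sample_ids),
    as_tibble(W),
    tibble(residual_norm = unname(residual))
  )
  attr(out, "W") <- W
  attr(out, "genes_used") <- shared
  attr(out, "genes_dropped") <- genes_dropped
  attr(out, "n_clamped") <- n_clamped
  attr(out, "scale_label") <- scale_label
  class(out) <- c("gep_projection", class(out))
  out
}

#' Compare projected usages across sample groups
#'
#' Kruskal-Wallis one-way analysis of variance of each programme's projected
#' usage across groups, with Benjamini-Hochberg correction across programmes;
#' pairwise Wilcoxon rank-sum tests (BH within each programme's family) are
#' run only for programmes significant in the omnibus test. Groups with
#' fewer than two samples are excluded with a warning.
#'
#' @param projection A `gep_projection` from [project_geps()] (or a usage
#'   matrix with sample rows).
#' @param groups Group label per sample.
#' @param fdr FDR threshold for the omnibus call (default 0.05).
#' @return A list with `omnibus` (tibble: `gep_id`, `kw_statistic`, `df`,
#'   `p_value`, `p_adjusted`, `significant`) and `pairwise` (tibble:
#'   `gep_id`, `group1`, `group2`, `p_value`, `p_adjusted`).
#' @export
summarise_projection_by_group <- function(projection, groups, fdr = 0.05) {
  W <- if (inherits(projection, "gep_projection")) attr(projection, "W") else
    as.matrix(projection)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(W))
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warn(sprintf("excluding group(s) with < 2 samples: %s",
                 paste(small, collapse = ", ")))
    keep <- !groups %in% small
    W <- W[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) abort("need at least 2 groups of size >= 2")
  g <- factor(groups)
  omnibus <- purrr::map_dfr(colnames(W), function(gep) {
    kw <- kruskal.test(W[, gep], g)
    tibble(gep_id = gep, kw_statistic = unname(kw$statistic),
           df = unname(kw$parameter), p_value = kw$p.value)
  })
  omnibus$p_adjusted <- p.adjust(omnibus$p_value, method = "BH")
  omnibus$significant <- omnibus$p_adjusted <= fdr
  pairwise <- purrr::map_dfr(omnibus$gep_id[omnibus$significant],
                             function(gep) {
    combos <- combn(levels(g), 2)
    pw <- purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
      g1 <- combos[1, ci]; g2 <- combos[2, ci]
      p <- suppressWarnings(wilcox.test(W[g == g1, gep],
                                        W[g == g2, gep]))$p.value
      tibble(gep_id = gep, group1 = g1, group2 = g2, p_value = p)
    })
    pw$p_adjusted <- p.adjust(pw$p_value, method = "BH")
    pw
  })
  list(omnibus = omnibus, pairwise = pairwise)
}
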