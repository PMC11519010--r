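#' Filter low-quality cells
#'
#' Removes cells expressing fewer than `min_genes` genes and cells whose
#' mitochondrial fraction exceeds `max_mito`. The removal conditions are
#' strict inequalities, so a cell detecting exactly `min_genes` genes or with
#' a mitochondrial fraction of exactly `max_mito` is retained. Cell order is
#' preserved.
#'
#' @param table A [cell_table()].
#' @param min_genes Minimum number of detected genes for retention
#'   (default 500).
#' @param max_mito Maximum tolerated mitochondrial fraction (default 0.60).
#' @return A filtered [cell_table()]; a warning reports the number of removed
#'   cells (an empty result is allowed).
#' @export
filter_cells <- function(table, min_genes = 500, max_mito = 0.60) {
  stopifnot(inherits(table, "cell_table"))
  if (min_genes <= 0 || max_mito <= 0) {
    abort("filter thresholds must be positive")
  }
  keep <- table$cell_meta$n_genes_detected >= min_genes &
    table$cell_meta$mito_fraction <= max_mito
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    warn(sprintf("filter_cells: removed %d of %d cells", n_removed,
                 length(keep)))
  }
  cell_table(table$counts[keep, , drop = FALSE],
             table$cell_meta[keep, , drop = FALSE])
}

#' Filter rarely detected genes
#'
#' Retains genes detected (nonzero) in at least `min_cells` cells and
#' recomputes each cell's detected-gene count on the reduced matrix.
#'
#' @param table A [cell_table()].
#' @param min_cells Minimum number of cells a gene must be detected in
#'   (default 3).
#' @return A filtered [cell_table()].
#' @export
filter_genes <- function(table, min_cells = 3) {
  stopifnot(inherits(table, "cell_table"))
  keep <- Matrix::colSums(table$counts > 0) >= min_cells
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    inform(sprintf("filter_genes: removed %d of %d genes", n_removed,
                   length(keep)))
  }
  cell_table(table$counts[, keep, drop = FALSE], table$cell_meta)
}

#' TP10K log-normalisation
#'
#' Scales each cell to 10,000 total counts (transcripts-per-10K) and applies
#' `log(1 + x)`. Before the log, every row sums to exactly 10,000.
#'
#' @param table A [cell_table()] with no all-zero cells (filter first).
#' @return A sparse real matrix of the same shape with entries
#'   `log(1 + 1e4 * count / cell_total)`.
#' @export
normalize_tp10k_log <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  totals <- Matrix::rowSums(table$counts)
  if (any(totals == 0)) {
    bad <- rownames(table$counts)[which(totals == 0)]
    abort(paste0("cells with zero total counts cannot be normalised: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  scaled <- Matrix::Diagonal(x = 1e4 / totals) %*% table$counts
  out <- scaled
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(table$counts)
  out
}

#' Per-sample pseudobulk profiles
#'
#' Sums counts over the cells of each sample (or any other grouping column of
#' the cell metadata), yielding a samples-by-genes integer matrix. Column
#' sums are conserved.
#'
#' @param table A [cell_table()].
#' @param by Name of the grouping column in `cell_meta` (default
#'   `"sample_id"`).
#' @return A dense base matrix, groups in rows, genes in columns.
#' @export
pseudobulk <- function(table, by = "sample_id") {
  stopifnot(inherits(table, "cell_table"))
  groups <- table$cell_meta[[by]]
  if (is.null(groups) || anyNA(groups)) {
    abort(sprintf("every cell must carry a non-missing '%s'", by))
  }
  f <- factor(groups, levels = unique(groups))
  ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                              dims = c(nlevels(f), length(f)))
  out <- as.matrix(ind %*% table$counts)
  rownames(out) <- levels(f)
  colnames(out) <- colnames(table$counts)
  out
}
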