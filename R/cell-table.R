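#' Construct a cell table
#'
#' A cell table couples a sparse cells-by-genes UMI count matrix with per-cell
#' annotations. `n_genes_detected` is always recomputed from the counts so the
#' invariant that it equals the number of nonzero entries per cell cannot be
#' violated by construction.
#'
#' @param counts Sparse (or dense) non-negative integer matrix, cells in rows,
#'   genes in columns, with row and column names.
#' @param cell_meta Data frame with one row per cell: `cell_id`, `sample_id`,
#'   `patient_id`, `compartment`, `mito_fraction`.
#' @return An object of class `cell_table` with elements `counts` and
#'   `cell_meta` (a tibble, including the recomputed `n_genes_detected`).
#' @export
cell_table <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) abort("counts must be non-negative")
  cell_meta <- as_tibble(cell_meta)
  required <- c("cell_id", "sample_id", "patient_id", "compartment",
                "mito_fraction")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols) > 0) {
    abort(paste("cell_meta lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cell_meta) != nrow(counts)) {
    abort("cell_meta must have one row per cell")
  }
  if (any(cell_meta$mito_fraction < 0 | cell_meta$mito_fraction > 1)) {
    abort("mito_fraction must lie in [0, 1]")
  }
  if (is.null(rownames(counts))) rownames(counts) <- cell_meta$cell_id
  cell_meta$n_genes_detected <- genes_detected(counts)
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_table")
}

genes_detected <- function(counts) {
  as.integer(rowSums(counts > 0))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells x %d genes (%d samples, %d compartments)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              length(unique(x$cell_meta$compartment))))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)
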