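# Plain-text interchange: 10x-style Matrix Market triplets with gene/barcode
# TSVs, metadata TSVs, and ground-truth arrays as named TSV files.

#' Write a cell table (and optional sample metadata) to a directory
#'
#' Counts are written as `matrix.mtx` (genes x cells, 10x convention) with
#' `features.tsv` and `barcodes.tsv`; per-cell annotations go to
#' `cell_meta.tsv` and, when given, per-sample metadata to `sample_meta.tsv`.
#'
#' @param table A [cell_table()].
#' @param dir Output directory (created if absent).
#' @param sample_meta Optional per-sample metadata tibble.
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(table, dir, sample_meta = NULL) {
  stopifnot(inherits(table, "cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(table$counts), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = colnames(table$counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = rownames(table$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(table$cell_meta, file.path(dir, "cell_meta.tsv"))
  if (!is.null(sample_meta)) {
    readr::write_tsv(sample_meta, file.path(dir, "sample_meta.tsv"))
  }
  invisible(dir)
}

#' Read a cell table written by [write_atlas()]
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and `cell_meta.tsv`.
#' @return A [cell_table()].
#' @export
read_atlas <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_names = "gene", show_col_types = FALSE)
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = "barcode", show_col_types = FALSE)
  dimnames(counts) <- list(barcodes$barcode, genes$gene)
  meta <- readr::read_tsv(file.path(dir, "cell_meta.tsv"),
                          show_col_types = FALSE)
  cell_table(counts, meta)
}

#' Write planted ground truth as named TSV arrays
#'
#' Each array of an `atlas_truth` object is written to its own tab-separated
#' file (`H_true.tsv`, `W_true.tsv`, `hub_assignment_true.tsv`,
#' `sample_mean_usage.tsv`, `inflamed_sample_ids.tsv`,
#' `remission_labels.tsv`), keeping the deliverable plain text.
#'
#' @param truth An `atlas_truth` object from [generate_atlas()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "atlas_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_named_matrix <- function(M, path, id_col) {
    df <- as_tibble(as.matrix(M), rownames = id_col)
    readr::write_tsv(df, path)
  }
  write_named_matrix(truth$H_true, file.path(dir, "H_true.tsv"), "gep_id")
  write_named_matrix(truth$W_true, file.path(dir, "W_true.tsv"), "cell_id")
  write_named_matrix(truth$sample_mean_usage,
                     file.path(dir, "sample_mean_usage.tsv"), "sample_id")
  readr::write_tsv(tibble(gep_id = names(truth$hub_assignment_true),
                          hub_id = unname(truth$hub_assignment_true)),
                   file.path(dir, "hub_assignment_true.tsv"))
  readr::write_tsv(tibble(sample_id = truth$inflamed_sample_ids),
                   file.path(dir, "inflamed_sample_ids.tsv"))
  readr::write_tsv(tibble(patient_id = names(truth$remission_labels),
                          remission = unname(truth$remission_labels)),
                   file.path(dir, "remission_labels.tsv"))
  invisible(dir)
}
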