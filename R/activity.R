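# Per-sample programme activity: empirical quantiles of a GEP's usage over
# the sample's cells of the GEP's own compartment.

DEFAULT_QUANTILES <- c(0.25, 0.5, 0.75, 0.95, 0.99)

# Build permutation strata: one per compartment, carrying the cell rows, their
# sample labels, and the columns of the usage matrix owned by the compartment.
build_strata <- function(W, cell_meta, gep_info) {
  if (is.null(gep_info)) {
    gep_info <- tibble(gep_id = colnames(W), compartment = "all")
    comp <- rep("all", nrow(cell_meta))
  } else {
    comp <- cell_meta$compartment
  }
  lapply(unique(gep_info$compartment), function(cp) {
    rows <- if (identical(cp, "all")) seq_len(nrow(cell_meta)) else
      which(comp == cp)
    list(compartment = cp,
         rows = rows,
         labels = cell_meta$sample_id[rows],
         gep_cols = match(gep_info$gep_id[gep_info$compartment == cp],
                          colnames(W)))
  })
}

# Quantile activity array (samples x geps x quantiles) plus per (sample, gep)
# cell counts, given possibly permuted sample labels per stratum.
compute_activity_array <- function(W, strata, sample_levels, probs,
                                   perm_labels = NULL) {
  S <- length(sample_levels)
  G <- ncol(W)
  A <- array(NA_real_, c(S, G, length(probs)),
             dimnames = list(sample_levels, colnames(W), NULL))
  ncells <- matrix(0L, S, G, dimnames = list(sample_levels, colnames(W)))
  for (si in seq_along(strata)) {
    st <- strata[[si]]
    labels <- if (is.null(perm_labels)) st$labels else perm_labels[[si]]
    groups <- split(st$rows, labels)
    for (s in names(groups)) {
      srow <- match(s, sample_levels)
      if (is.na(srow)) next
      ix <- groups[[s]]
      for (g in st$gep_cols) {
        A[srow, g, ] <- quantile7(W[ix, g], probs)
      }
      ncells[srow, st$gep_cols] <- length(ix)
    }
  }
  list(A = A, n_cells = ncells)
}

#' Summarise programme activity as per-sample quantiles
#'
#' For each sample and programme, computes empirical quantiles (linear
#' interpolation) of the programme's usage over the sample's cells of the
#' programme's compartment. Samples with fewer cells than `min_cells` are
#' flagged; samples with no cells of the compartment get missing values.
#'
#' @param W Cells x programmes usage matrix with cell ids as row names and
#'   programme ids as column names.
#' @param cell_meta Tibble with `cell_id`, `sample_id` and `compartment`, one
#'   row per row of `W`.
#' @param gep_info Tibble mapping `gep_id` to `compartment`; `NULL` treats all
#'   cells as one compartment.
#' @param quantiles Probabilities to evaluate (default 0.25, 0.5, 0.75, 0.95,
#'   0.99).
#' @param min_cells Minimum cells per (sample, programme) before the
#'   `low_cells` flag is raised (default 10).
#' @return A tibble with `sample_id`, `gep_id`, `quantile`, `activity`,
#'   `n_cells`, `low_cells`; missing compartment/sample combinations appear
#'   with `NA` activity. The quantile grid is recorded in the `"quantiles"`
#'   attribute.
#' @export
activity_quantiles <- function(W, cell_meta,
                               gep_info = NULL,
                               quantiles = DEFAULT_QUANTILES,
                               min_cells = 10) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == nrow(cell_meta))
  if (any(W < 0)) abort("usages must be non-negative")
  if (anyNA(cell_meta$sample_id)) abort("every cell must carry a sample_id")
  sample_levels <- sort(unique(cell_meta$sample_id))
  strata <- build_strata(W, cell_meta, gep_info)
  res <- compute_activity_array(W, strata, sample_levels, quantiles)
  out <- purrr::map_dfr(seq_along(quantiles), function(qi) {
    tibble(
      sample_id = rep(sample_levels, times = ncol(W)),
      gep_id = rep(colnames(W), each = length(sample_levels)),
      quantile = quantiles[qi],
      activity = as.vector(res$A[, , qi]),
      n_cells = as.vector(res$n_cells)
    )
  })
  out <- out |>
    mutate(low_cells = .data$n_cells < min_cells) |>
    arrange(.data$gep_id, .data$sample_id, .data$quantile)
  n_missing <- sum(is.na(out$activity)) / length(quantiles)
  if (n_missing > 0) {
    inform(sprintf(
      "activity_quantiles: %d (sample, GEP) combinations have no cells",
      as.integer(n_missing)))
  }
  attr(out, "quantiles") <- quantiles
  out
}
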