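# Composite inflammation score: single-sample rank-based enrichment of a gene
# signature, min-max scaled to 0-10 across the cohort, with a cutoff at the
# maximum healthy-sample score.

# ssGSEA-style running-sum enrichment of one signature in one expression
# vector: genes are ranked within the sample, signature steps are weighted by
# rank^alpha, and the score integrates the difference between the weighted
# in-signature ECDF and the uniform out-of-signature ECDF.
ssgsea_running_sum <- function(expr, in_sig, alpha = 0.25) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  w <- r[ord]^alpha
  sig <- in_sig[ord]
  p_in <- cumsum(ifelse(sig, w, 0)) / sum(w[sig])
  p_out <- cumsum(!sig) / (n - sum(sig))
  sum(p_in - p_out)
}

#' Composite inflammation score
#'
#' Scores each sample by a single-sample rank-based running-sum enrichment of
#' the signature (rank weighting exponent `alpha`), then min-max scales the
#' raw scores to \[0, 10\] across the cohort. The cutoff is the maximum score
#' among healthy samples, a heuristic threshold above which a sample is
#' called inflamed. Scores depend on expression only through within-sample
#' ranks, and are comparable only within the scored cohort.
#'
#' @param pseudobulk Samples x genes matrix (sample ids as row names), e.g.
#'   from [pseudobulk()].
#' @param signature Character vector of signature gene names (non-empty;
#'   must intersect the measured genes).
#' @param healthy_ids Sample ids of the healthy reference samples (>= 1).
#' @param alpha Rank weighting exponent (default 0.25).
#' @return An `inflammation_scores` tibble: `sample_id`, `raw`, `score` (0-10),
#'   `is_healthy`, `above_cutoff`; the cutoff is in the `"cutoff"` attribute.
#' @export
inflammation_score <- function(pseudobulk, signature, healthy_ids,
                               alpha = 0.25) {
  X <- as.matrix(pseudobulk)
  if (nrow(X) < 2) abort("at least 2 samples are required")
  if (length(signature) == 0 || anyDuplicated(signature) > 0) {
    abort("signature must be a non-empty set of unique gene ids")
  }
  if (!all(healthy_ids %in% rownames(X)) || length(healthy_ids) == 0) {
    abort("healthy_ids must name at least one scored sample")
  }
  in_sig <- colnames(X) %in% signature
  if (!any(in_sig)) abort("signature shares no genes with the expression matrix")
  if (all(in_sig)) abort("signature covers every measured gene; score undefined")
  raw <- apply(X, 1, ssgsea_running_sum, in_sig = in_sig, alpha = alpha)
  rng <- range(raw)
  score <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) * 10 else
    rep(0, length(raw))
  is_healthy <- rownames(X) %in% healthy_ids
  cutoff <- max(score[is_healthy])
  out <- tibble(
    sample_id = rownames(X),
    raw = unname(raw),
    score = unname(score),
    is_healthy = is_healthy,
    above_cutoff = unname(score > cutoff)
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("inflammation_scores", class(out))
  out
}

#' Read a gene signature from a plain-text or GMT file
#'
#' One gene per line, or a single GMT record (name, description, genes).
#'
#' @param path File path.
#' @param gmt Interpret the file as GMT (default guesses by extension).
#' @return Character vector of gene ids.
#' @export
read_signature <- function(path, gmt = grepl("\\.gmt$", path,
                                             ignore.case = TRUE)) {
  if (gmt) {
    fields <- strsplit(readLines(path, n = 1), "\t")[[1]]
    if (length(fields) < 3) abort("malformed GMT record")
    unique(fields[-(1:2)])
  } else {
    unique(trimws(readLines(path)))
  }
}
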