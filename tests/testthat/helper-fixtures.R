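# Shared fixture builders. Everything is generated in code at test time.

# Small atlas used by several suites (8 samples, 3 compartments, 12 GEPs).
tiny_atlas <- function(seed = 7, ...) {
  generate_atlas(atlas_config(n_patients = 4, samples_per_patient = 2,
                              cells_per_sample = 30, n_genes = 120,
                              seed = seed, ...))
}

# Cell table with prescribed detected-gene counts and mito fractions; each
# cell detects `n_detected[i]` genes (one count each).
make_cell_table <- function(n_detected, mito, n_genes = max(n_detected) + 5) {
  n <- length(n_detected)
  counts <- matrix(0, n, n_genes,
                   dimnames = list(sprintf("c%03d", seq_len(n)),
                                   sprintf("g%03d", seq_len(n_genes))))
  for (i in seq_len(n)) counts[i, seq_len(n_detected[i])] <- 1
  meta <- tibble::tibble(
    cell_id = rownames(counts),
    sample_id = rep_len(c("sA", "sB"), n),
    patient_id = rep_len(c("p1", "p2"), n),
    compartment = "E",
    mito_fraction = mito
  )
  cell_table(counts, meta)
}

# Planted exactly-factorisable matrix with disjoint spectra blocks.
planted_nmf <- function(n = 200, m = 50, k = 3, seed = 42, noise_sd = 0) {
  set.seed(seed)
  W0 <- matrix(rgamma(n * k, 2), n, k)
  H0 <- matrix(0, k, m)
  block <- floor(m / k)
  for (j in seq_len(k)) {
    H0[j, ((j - 1) * block + 1):(j * block)] <- rgamma(block, 5)
  }
  X <- W0 %*% H0
  if (noise_sd > 0) X <- X + matrix(abs(rnorm(n * m, 0, noise_sd)), n, m)
  list(X = X, W0 = W0, H0 = H0)
}

# All distinct arrangements of a multiset (used by the exhaustive permutation
# oracle; e.g. sample labels 1,1,2,2,3,3,4,4).
multiset_permutations <- function(x) {
  x <- sort(x)
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in unique(remaining)) {
      recurse(c(prefix, v), remaining[-match(v, remaining)])
    }
  }
  recurse(c(), x)
  out
}
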