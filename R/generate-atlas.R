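#' Generate a synthetic single-cell atlas with planted ground truth
#'
#' Simulates a compartment-structured UMI count matrix from planted
#' non-negative programme spectra and usages, together with a longitudinal
#' clinical metadata table and the full ground truth (spectra, usages, hub
#' structure, inflamed samples, remission labels).
#'
#' Per-sample mean usages are log-normal: GEPs belonging to the same planted
#' hub share a per-sample latent factor whose weight is set by
#' `within_hub_usage_correlation`, which induces the sample-level covariation
#' that hub discovery is designed to detect. GEPs listed in
#' `inflammation_effect_geps` have their mean usage multiplied by
#' `1 + inflammation_effect_size` in inflamed samples, and signature genes are
#' upregulated by `signature_effect_size`-fold there. Counts are drawn by
#' gamma-perturbed multinomial sampling: each cell's library size is drawn
#' first and gene probabilities proportional to the planted rate
#' `W_true %*% H_true` are jittered by Gamma(dispersion, dispersion)
#' multipliers, giving negative-binomial-style overdispersion while the total
#' count of every cell equals its drawn library size exactly
#' (`noise_dispersion = Inf` gives the Poisson-multinomial limit).
#'
#' @param config An [atlas_config()] object.
#' @return A list with elements `cells` (a [cell_table()]), `samples`
#'   (a tibble of per-sample clinical metadata), and `truth` (an
#'   `atlas_truth` list carrying `H_true`, `W_true`, `hub_assignment_true`,
#'   `inflamed_sample_ids`, `remission_labels`, `sample_mean_usage`,
#'   `gep_info`, and the config).
#' @examples
#' atlas <- generate_atlas(atlas_config(n_patients = 4, cells_per_sample = 20,
#'                                      n_genes = 120, seed = 7))
#' atlas$cells
#' @export
generate_atlas <- function(config) {
  if (!inherits(config, "atlas_config")) {
    abort("config must be an atlas_config object")
  }
  config <- validate_atlas_config(config)
  with_seed(config$seed, generate_atlas_impl(config))
}

generate_atlas_impl <- function(cfg) {
  gene_names <- sprintf("g%04d", seq_len(cfg$n_genes))
  gep_ids <- gep_ids_for(cfg$compartments, cfg$k_true)
  gep_comp <- rep(cfg$compartments, each = cfg$k_true)
  names(gep_comp) <- gep_ids
  n_gep <- length(gep_ids)
  hub <- cfg$hub_assignment_true[gep_ids]

  ## planted spectra: disjoint gene blocks (outside the signature set) on a
  ## uniform background, rows normalised to sum 1 so they act as gene
  ## probabilities
  sig_idx <- match(cfg$signature_genes, gene_names)
  free_genes <- setdiff(seq_len(cfg$n_genes), sig_idx)
  blocks <- split(free_genes,
                  rep_len(seq_len(n_gep), length(free_genes)))
  H_true <- matrix(0.25 / cfg$n_genes, nrow = n_gep, ncol = cfg$n_genes,
                   dimnames = list(gep_ids, gene_names))
  for (g in seq_len(n_gep)) {
    blk <- blocks[[g]]
    H_true[g, blk] <- H_true[g, blk] +
      rgamma(length(blk), shape = 5, rate = 1) / length(blk) * 3
  }
  H_true <- H_true / rowSums(H_true)

  ## sample / patient hierarchy with clinical metadata
  n_samples <- cfg$n_patients * cfg$samples_per_patient
  patient_ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  sample_patient <- rep(patient_ids, each = cfg$samples_per_patient)
  timepoint <- rep_len(c("pre", "post"), cfg$samples_per_patient)
  timepoint <- rep(timepoint, times = cfg$n_patients)
  n_inflamed <- max(1L, min(n_samples - 1L,
                            round(cfg$inflamed_fraction * n_samples)))
  inflamed <- rep(FALSE, n_samples)
  inflamed[sample.int(n_samples, n_inflamed)] <- TRUE

  disease <- rep_len(c("CD", "UC"), cfg$n_patients)[match(sample_patient,
                                                          patient_ids)]
  n_remission <- round(cfg$remission_fraction * cfg$n_patients)
  remission <- setNames(rep(FALSE, cfg$n_patients), patient_ids)
  remission[sample.int(cfg$n_patients, n_remission)] <- TRUE

  sites <- c("terminal_ileum", "ascending_colon", "descending_colon",
             "sigmoid", "rectum")
  sample_meta <- tibble(
    sample_id = sample_ids,
    patient_id = sample_patient,
    disease = disease,
    site = sample(sites, n_samples, replace = TRUE),
    inflamed = inflamed,
    timepoint = timepoint,
    age = round(pmin(pmax(rnorm(n_samples, 45, 12), 18), 85))[
      match(sample_patient, sample_patient)],
    sex = sample(c("F", "M"), cfg$n_patients, replace = TRUE)[
      match(sample_patient, patient_ids)],
    disease_duration = round(rgamma(cfg$n_patients, 2, 0.4), 1)[
      match(sample_patient, patient_ids)],
    HBI = rpois(n_samples, ifelse(inflamed, 7, 2)),
    SSCAI = rpois(n_samples, ifelse(inflamed, 5, 1)),
    UCEIS = pmin(rpois(n_samples, ifelse(inflamed, 4, 1)), 8L),
    Nancy = pmin(rpois(n_samples, ifelse(inflamed, 2.5, 0.5)), 4L),
    ulcers_present = inflamed & runif(n_samples) < 0.6,
    remission = unname(remission[sample_patient])
  )

  ## per-sample mean usage: shared hub latent + independent noise on the log
  ## scale, then the planted inflammation shift on affected GEPs
  rho <- cfg$within_hub_usage_correlation
  hub_levels <- sort(unique(hub))
  f_hub <- matrix(rnorm(n_samples * length(hub_levels)), n_samples,
                  dimnames = list(sample_ids, hub_levels))
  eps <- matrix(rnorm(n_samples * n_gep), n_samples, n_gep,
                dimnames = list(sample_ids, gep_ids))
  z <- sqrt(rho) * f_hub[, as.character(hub), drop = FALSE] +
    sqrt(1 - rho) * eps
  m <- exp(cfg$usage_sd * z - cfg$usage_sd^2 / 2)
  dimnames(m) <- list(sample_ids, gep_ids)
  affected <- gep_ids %in% cfg$inflammation_effect_geps
  m[inflamed, affected] <- m[inflamed, affected] *
    (1 + cfg$inflammation_effect_size)

  ## cells: per compartment within each sample; usages gamma around the
  ## per-sample mean, zero outside the cell's own compartment
  cell_rows <- expand.grid(cell = seq_len(cfg$cells_per_sample),
                           compartment = cfg$compartments,
                           sample_id = sample_ids,
                           stringsAsFactors = FALSE)
  n_cells <- nrow(cell_rows)
  cell_ids <- sprintf("C%06d", seq_len(n_cells))
  W_true <- matrix(0, n_cells, n_gep, dimnames = list(cell_ids, gep_ids))
  cell_shape <- 4
  for (cp in cfg$compartments) {
    rows <- which(cell_rows$compartment == cp)
    cols <- which(gep_comp == cp)
    mu <- m[cell_rows$sample_id[rows], cols, drop = FALSE]
    W_true[rows, cols] <- rgamma(length(mu), shape = cell_shape,
                                 rate = cell_shape) * mu
  }

  rate <- W_true %*% H_true
  cell_inflamed <- inflamed[match(cell_rows$sample_id, sample_ids)]
  rate[cell_inflamed, sig_idx] <- rate[cell_inflamed, sig_idx] *
    cfg$signature_effect_size
  if (is.finite(cfg$noise_dispersion)) {
    rate <- rate * matrix(rgamma(length(rate), shape = cfg$noise_dispersion,
                                 rate = cfg$noise_dispersion),
                          nrow = n_cells)
  }
  lib <- pmax(rnbinom(n_cells, mu = cfg$library_size_mean, size = 20), 100L)
  counts <- vapply(seq_len(n_cells), function(i) {
    rmultinom(1, lib[i], rate[i, ])[, 1]
  }, numeric(cfg$n_genes))
  counts <- Matrix::Matrix(base::t(counts), sparse = TRUE,
                           dimnames = list(cell_ids, gene_names))

  cell_meta <- tibble(
    cell_id = cell_ids,
    sample_id = cell_rows$sample_id,
    patient_id = sample_patient[match(cell_rows$sample_id, sample_ids)],
    compartment = cell_rows$compartment,
    mito_fraction = stats::rbeta(n_cells, 2, 18)
  )

  truth <- structure(list(
    H_true = H_true,
    W_true = W_true,
    hub_assignment_true = hub,
    inflamed_sample_ids = sample_ids[inflamed],
    remission_labels = remission,
    sample_mean_usage = m,
    gep_info = tibble(gep_id = gep_ids, compartment = unname(gep_comp),
                      hub_true = unname(hub)),
    library_sizes = setNames(lib, cell_ids),
    config = cfg
  ), class = "atlas_truth")

  list(cells = cell_table(counts, cell_meta),
       samples = sample_meta,
       truth = truth)
}

#' Generate bulk expression profiles from fixed programme spectra
#'
#' Draws non-negative per-sample usages and composes bulk profiles as
#' `W_bulk %*% H_true` plus Gaussian noise truncated at zero, for testing
#' fixed-spectra projection.
#'
#' @param H_true Non-negative spectra matrix, programmes in rows.
#' @param n_samples Number of bulk samples.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return A list with `bulk` (samples x genes) and `W_bulk_true`
#'   (samples x programmes).
#' @export
generate_bulk_from_geps <- function(H_true, n_samples, noise_sd = 0,
                                    seed = 1L) {
  if (any(H_true < 0)) abort("H_true must be non-negative")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  with_seed(seed, {
    k <- nrow(H_true)
    W_bulk <- matrix(rgamma(n_samples * k, shape = 2, rate = 0.5),
                     n_samples, k)
    rownames(W_bulk) <- sprintf("B%03d", seq_len(n_samples))
    colnames(W_bulk) <- rownames(H_true)
    bulk <- W_bulk %*% H_true
    if (noise_sd > 0) {
      bulk <- pmax(bulk + matrix(rnorm(length(bulk), 0, noise_sd),
                                 nrow = n_samples), 0)
    }
    colnames(bulk) <- colnames(H_true)
    list(bulk = bulk, W_bulk_true = W_bulk)
  })
}

#' @export
print.atlas_truth <- function(x, ...) {
  cat(sprintf(
    "<atlas_truth> %d GEPs in %d hubs; %d inflamed samples; %d genes\n",
    nrow(x$H_true), length(unique(x$hub_assignment_true)),
    length(x$inflamed_sample_ids), ncol(x$H_true)))
  invisible(x)
}
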