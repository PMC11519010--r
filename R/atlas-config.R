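#' Configuration for a synthetic single-cell atlas
#'
#' Collects and validates all parameters of the synthetic-atlas generator.
#' Defaults describe a small IBD-like longitudinal cohort: 20 patients with
#' two gut samples each (one pre-, one post-treatment), three cell
#' compartments, four gene expression programmes (GEPs) per compartment, and
#' the twelve GEPs organised into three covarying hubs that cut across
#' compartments.
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Samples collected per patient (alternating
#'   pre/post timepoints).
#' @param cells_per_sample Cells per compartment within each sample.
#' @param n_genes Number of genes; must be at least `10 * k_true`.
#' @param compartments Character labels of the cell compartments; each defines
#'   a permutation stratum and owns `k_true` programmes.
#' @param k_true Number of planted programmes per compartment (>= 2).
#' @param hub_assignment_true Named integer vector mapping every GEP id to a
#'   hub id; `NULL` assigns GEPs round-robin into `n_hubs` hubs so that hubs
#'   span compartments.
#' @param n_hubs Number of hubs used when `hub_assignment_true` is `NULL`.
#' @param within_hub_usage_correlation Target correlation, in \[0, 1), of the
#'   shared latent factor driving per-sample mean usages of GEPs in the same
#'   hub.
#' @param inflamed_fraction Fraction of samples labelled inflamed, in (0, 1).
#' @param inflammation_effect_geps GEP ids whose mean usage is elevated in
#'   inflamed samples; `NULL` picks the members of hub 1.
#' @param inflammation_effect_size Multiplicative usage elevation (fold change
#'   minus one is the planted effect) for affected GEPs in inflamed samples.
#' @param signature_genes Gene names upregulated in inflamed samples
#'   independently of programme structure; `NULL` takes the last 25 genes.
#' @param signature_effect_size Fold change of signature genes in inflamed
#'   samples.
#' @param usage_sd Log-scale standard deviation of per-sample mean usages.
#' @param noise_dispersion Gamma shape of the per-entry overdispersion
#'   multiplier; `Inf` gives Poisson-multinomial counts.
#' @param library_size_mean Mean UMI count per cell.
#' @param remission_fraction Fraction of patients labelled as reaching
#'   remission.
#' @param seed Integer seed making the generator fully reproducible.
#' @return An object of class `atlas_config`.
#' @export
atlas_config <- function(n_patients = 20,
                         samples_per_patient = 2,
                         cells_per_sample = 100,
                         n_genes = 300,
                         compartments = c("M", "S", "E"),
                         k_true = 4,
                         hub_assignment_true = NULL,
                         n_hubs = 3,
                         within_hub_usage_correlation = 0.7,
                         inflamed_fraction = 0.5,
                         inflammation_effect_geps = NULL,
                         inflammation_effect_size = 1,
                         signature_genes = NULL,
                         signature_effect_size = 2,
                         usage_sd = 0.6,
                         noise_dispersion = 10,
                         library_size_mean = 2000,
                         remission_fraction = 0.5,
                         seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    samples_per_patient = as.integer(samples_per_patient),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes),
    compartments = as.character(compartments),
    k_true = as.integer(k_true),
    hub_assignment_true = hub_assignment_true,
    n_hubs = as.integer(n_hubs),
    within_hub_usage_correlation = within_hub_usage_correlation,
    inflamed_fraction = inflamed_fraction,
    inflammation_effect_geps = inflammation_effect_geps,
    inflammation_effect_size = inflammation_effect_size,
    signature_genes = signature_genes,
    signature_effect_size = signature_effect_size,
    usage_sd = usage_sd,
    noise_dispersion = noise_dispersion,
    library_size_mean = library_size_mean,
    remission_fraction = remission_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "atlas_config"
  validate_atlas_config(cfg)
}

gep_ids_for <- function(compartments, k_true) {
  unlist(lapply(compartments, function(cp) {
    sprintf("p%s%02d", cp, seq_len(k_true))
  }))
}

validate_atlas_config <- function(cfg) {
  if (cfg$k_true < 2L) {
    abort("invalid config: k_true must be >= 2")
  }
  if (cfg$n_genes < 10L * cfg$k_true) {
    abort("invalid config: n_genes must be >= 10 * k_true")
  }
  if (cfg$within_hub_usage_correlation < 0 ||
      cfg$within_hub_usage_correlation >= 1) {
    abort("invalid config: within_hub_usage_correlation must lie in [0, 1)")
  }
  if (cfg$inflamed_fraction <= 0 || cfg$inflamed_fraction >= 1) {
    abort("invalid config: inflamed_fraction must lie in (0, 1)")
  }
  if (!is.finite(cfg$noise_dispersion) && !is.infinite(cfg$noise_dispersion)) {
    abort("invalid config: noise_dispersion must be a positive real")
  }
  if (cfg$noise_dispersion <= 0) {
    abort("invalid config: noise_dispersion must be a positive real")
  }
  geps <- gep_ids_for(cfg$compartments, cfg$k_true)
  if (is.null(cfg$hub_assignment_true)) {
    cfg$hub_assignment_true <- setNames(
      rep_len(seq_len(cfg$n_hubs), length(geps)), geps)
  }
  hub <- cfg$hub_assignment_true
  if (is.null(names(hub)) || !setequal(names(hub), geps) ||
      anyDuplicated(names(hub)) > 0) {
    abort(paste("invalid config: hub_assignment_true must assign every GEP",
                "to exactly one hub"))
  }
  if (is.null(cfg$inflammation_effect_geps)) {
    cfg$inflammation_effect_geps <- names(hub)[hub == hub[[1]]]
  }
  if (!all(cfg$inflammation_effect_geps %in% geps)) {
    abort("invalid config: inflammation_effect_geps must be a subset of GEPs")
  }
  gene_names <- sprintf("g%04d", seq_len(cfg$n_genes))
  if (is.null(cfg$signature_genes)) {
    cfg$signature_genes <- utils::tail(gene_names, 25)
  }
  if (!all(cfg$signature_genes %in% gene_names)) {
    abort("invalid config: signature_genes must be drawn from g0001..")
  }
  cfg
}

#' @export
print.atlas_config <- function(x, ...) {
  geps <- gep_ids_for(x$compartments, x$k_true)
  cat("<atlas_config>\n")
  cat(sprintf("  %d patients x %d samples, %d cells/compartment, %d genes\n",
              x$n_patients, x$samples_per_patient, x$cells_per_sample,
              x$n_genes))
  cat(sprintf("  %d GEPs (%d per compartment: %s) in %d hubs\n",
              length(geps), x$k_true,
              paste(x$compartments, collapse = ", "),
              length(unique(x$hub_assignment_true))))
  cat(sprintf("  within-hub correlation %.2f, inflamed fraction %.2f, seed %d\n",
              x$within_hub_usage_correlation, x$inflamed_fraction, x$seed))
  invisible(x)
}
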