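# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a consensus GEP model
#'
#' Returns the consensus spectra in long form: one row per (programme, gene)
#' with the spectrum weight and the gene's rank within the programme.
#'
#' @param x A `gep_model` from [consensus_factorize()].
#' @param ... Unused.
#' @return A tibble with `gep_id`, `gene`, `weight`, `rank`.
#' @export
tidy.gep_model <- function(x, ...) {
  as_tibble(x$H, rownames = "gep_id") |>
    tidyr::pivot_longer(-"gep_id", names_to = "gene", values_to = "weight") |>
    group_by(.data$gep_id) |>
    mutate(rank = rank(-.data$weight, ties.method = "first")) |>
    ungroup()
}

#' One-row summary of a consensus GEP model
#'
#' @param x A `gep_model`.
#' @param ... Unused.
#' @return A tibble with `k`, `silhouette`, `frobenius_error`, `n_outliers`,
#'   `n_restarts`, `solver`.
#' @export
glance.gep_model <- function(x, ...) {
  tibble(k = x$k, silhouette = x$silhouette,
         frobenius_error = x$frobenius_error,
         n_outliers = sum(x$outlier_mask),
         n_restarts = x$n_restarts, solver = x$solver)
}

#' Tidy a hub partition
#'
#' @param x A `hub_partition` from [detect_hubs()].
#' @param ... Unused.
#' @return The assignment tibble (`gep_id`, `hub_id`, and `inflammatory` when
#'   labelled).
#' @export
tidy.hub_partition <- function(x, ...) {
  as_tibble(x$assignment)
}

#' One-row summary of a hub partition
#'
#' @param x A `hub_partition`.
#' @param ... Unused.
#' @return A tibble with `n_geps`, `n_hubs`, `modularity`,
#'   `n_inflammatory_hubs`.
#' @export
glance.hub_partition <- function(x, ...) {
  tibble(n_geps = nrow(x$assignment),
         n_hubs = length(unique(x$assignment$hub_id)),
         modularity = x$modularity,
         n_inflammatory_hubs = if (is.null(x$inflammatory)) NA_integer_ else
           sum(x$inflammatory))
}
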