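# ggplot2 displays for the main result types.

#' Plot k-selection diagnostics
#'
#' Silhouette and Frobenius reconstruction error against the candidate number
#' of programmes, as returned by [select_k()].
#'
#' @param diagnostics The `diagnostics` tibble from [select_k()].
#' @return A ggplot object (two free-scale panels).
#' @export
plot_k_selection <- function(diagnostics) {
  long <- diagnostics |>
    select("k", "silhouette", "frobenius_error") |>
    tidyr::pivot_longer(-"k", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of programmes (k)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a hub partition as a signed network
#'
#' Nodes coloured by hub, solid edges for positive and dashed for negative
#' associations, edge width proportional to |weight|.
#'
#' @param object A `hub_partition` from [detect_hubs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hub_partition <- function(object, ...) {
  g <- object$graph
  lay <- igraph::layout_with_fr(
    g, weights = abs(igraph::E(g)$weight) + 1e-6)
  nodes <- tibble(
    gep_id = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2]
  ) |>
    left_join(object$assignment, by = "gep_id")
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(
    x = nodes$x[match(el$from, nodes$gep_id)],
    y = nodes$y[match(el$from, nodes$gep_id)],
    xend = nodes$x[match(el$to, nodes$gep_id)],
    yend = nodes$y[match(el$to, nodes$gep_id)],
    weight = el$weight,
    sign = ifelse(el$weight >= 0, "positive", "negative")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign,
                   linewidth = abs(.data$weight)),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = factor(.data$hub_id)), size = 4) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gep_id),
      vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::labs(colour = "hub", linetype = NULL) +
    ggplot2::theme_void()
}

#' Plot inflammation scores with the healthy-derived cutoff
#'
#' @param object An `inflammation_scores` tibble from [inflammation_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inflammation_scores <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  df <- as_tibble(object) |>
    mutate(group = ifelse(.data$is_healthy, "healthy", "disease"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.15, height = 0,
                         ggplot2::aes(colour = .data$above_cutoff)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(y = "inflammation score (0-10)", x = NULL,
                  colour = "above cutoff") +
    ggplot2::theme_minimal()
}

#' Plot per-sample programme activity
#'
#' Median-quantile activity per sample, split by inflammation status.
#'
#' @param activity Long activity tibble from [activity_quantiles()].
#' @param sample_meta Tibble with `sample_id` and `inflamed`.
#' @param geps Optional subset of programme ids.
#' @return A ggplot object.
#' @export
plot_activity <- function(activity, sample_meta, geps = NULL) {
  df <- activity |>
    filter(.data$quantile == 0.5) |>
    left_join(sample_meta, by = "sample_id")
  if (!is.null(geps)) df <- df |> filter(.data$gep_id %in% geps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inflamed, y = .data$activity)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::facet_wrap(~gep_id, scales = "free_y") +
    ggplot2::labs(x = "inflamed", y = "median usage per sample") +
    ggplot2::theme_minimal()
}
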