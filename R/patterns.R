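# Six-pattern taxonomy of longitudinal cell-abundance changes across
# treatment, by remission outcome, plus a simplified differential-abundance
# test that feeds it.

PATTERN_LEVELS_BASELINE <- c("higher_in_R", "higher_in_NR", "none")
PATTERN_LEVELS_CHANGE <- c("up", "down", "none")

#' Classify a longitudinal abundance pattern
#'
#' Maps the categorical outcomes of the upstream abundance tests (baseline
#' difference between remission and nonremission; post-treatment change in
#' each group) to one of six patterns:
#' \describe{
#'   \item{1}{high at baseline in both groups, decreases in remission only}
#'   \item{2}{decreases in nonremission (unchanged or decreased in remission)}
#'   \item{3}{higher at baseline in remission and decreases there}
#'   \item{4}{concordant increase in both groups}
#'   \item{5}{increases in remission only}
#'   \item{6}{increases in nonremission only, with no baseline difference}
#' }
#' Rules are evaluated in the fixed precedence order 3, 1, 4, 5, 6, 2
#' (baseline-difference rules first, then concordant, then discordant); the
#' first match wins and anything else is `"unclassified"`. Inputs are
#' vectorised.
#'
#' @param baseline_diff One of `"higher_in_R"`, `"higher_in_NR"`, `"none"`.
#' @param change_R,change_NR One of `"up"`, `"down"`, `"none"`: the
#'   post-treatment change in the remission / nonremission group.
#' @return Character vector of `"1"`..`"6"` or `"unclassified"`.
#' @export
classify_pattern <- function(baseline_diff, change_R, change_NR) {
  n <- max(length(baseline_diff), length(change_R), length(change_NR))
  baseline_diff <- rep_len(baseline_diff, n)
  change_R <- rep_len(change_R, n)
  change_NR <- rep_len(change_NR, n)
  if (!all(baseline_diff %in% PATTERN_LEVELS_BASELINE)) {
    abort("baseline_diff must be one of higher_in_R, higher_in_NR, none")
  }
  if (!all(change_R %in% PATTERN_LEVELS_CHANGE) ||
      !all(change_NR %in% PATTERN_LEVELS_CHANGE)) {
    abort("changes must be one of up, down, none")
  }
  out <- rep("unclassified", n)
  rules <- list(
    list("3", baseline_diff == "higher_in_R" & change_R == "down"),
    list("1", baseline_diff == "none" & change_R == "down" &
           change_NR == "none"),
    list("4", change_R == "up" & change_NR == "up"),
    list("5", change_R == "up" & change_NR == "none"),
    list("6", baseline_diff == "none" & change_R == "none" &
           change_NR == "up"),
    list("2", change_NR == "down" & change_R %in% c("none", "down"))
  )
  for (rule in rules) {
    hit <- rule[[2]] & out == "unclassified"
    out[hit] <- rule[[1]]
  }
  out
}

#' Simplified differential-abundance test per cell state
#'
#' For each cell state, models per-sample state membership against a
#' two-level grouping with a binomial mixed model (random intercept per
#' patient); if the mixed fit fails, falls back to a linear model on
#' per-sample proportions, with a warning. P-values are Benjamini-Hochberg
#' adjusted across states; the signed direction and significance are the
#' inputs to [classify_pattern()].
#'
#' @param cell_counts Tibble with `sample_id`, `state`, `count` (cells of the
#'   state in the sample), or a samples x states matrix.
#' @param meta Tibble with `sample_id`, `patient_id`, and the grouping column.
#' @param grouping Name of a two-level grouping column in `meta` (its second
#'   sorted level is the "up" direction).
#' @param fdr FDR threshold (default 0.05).
#' @return A tibble with `state`, `estimate`, `p_value`, `p_adjusted`,
#'   `significant`, `direction` (`"up"`, `"down"` or `"none"`), `untestable`.
#' @export
abundance_change_test <- function(cell_counts, meta, grouping, fdr = 0.05) {
  if (is.matrix(cell_counts)) {
    cell_counts <- as_tibble(cell_counts, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "state",
                          values_to = "count")
  }
  stopifnot(all(c("sample_id", "state", "count") %in% names(cell_counts)))
  if (!grouping %in% names(meta)) abort("grouping column not found in meta")
  g <- meta[[grouping]]
  lv <- sort(unique(as.character(g[!is.na(g)])))
  if (length(lv) != 2) abort("grouping must have exactly two levels")
  if (any(table(as.character(g)) < 2)) {
    abort("need at least 2 samples per group")
  }
  totals <- cell_counts |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  df <- cell_counts |>
    left_join(totals, by = "sample_id") |>
    left_join(meta, by = "sample_id") |>
    mutate(group = factor(as.character(.data[[grouping]]), levels = lv))

  fit_state <- function(d) {
    if (all(d$count == 0) || any(tapply(d$count, d$group, sum) == 0)) {
      return(tibble(estimate = NA_real_, p_value = NA_real_,
                    untestable = TRUE))
    }
    fit <- tryCatch({
      m <- suppressMessages(suppressWarnings(lme4::glmer(
        cbind(count, total - count) ~ group + (1 | patient_id),
        data = d, family = stats::binomial)))
      cf <- stats::coef(summary(m))
      list(est = cf[2, "Estimate"], p = cf[2, "Pr(>|z|)"])
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warn("binomial mixed fit failed; falling back to linear model on proportions")
      m <- lm(I(count / total) ~ group, data = d)
      cf <- stats::coef(summary(m))
      fit <- list(est = cf[2, "Estimate"], p = cf[2, "Pr(>|t|)"])
    }
    tibble(estimate = fit$est, p_value = fit$p, untestable = FALSE)
  }

  out <- df |>
    dplyr::group_split(.data$state) |>
    purrr::map_dfr(function(d) {
      dplyr::bind_cols(tibble(state = d$state[[1]]), fit_state(d))
    })
  out$p_adjusted <- NA_real_
  ok <- !out$untestable
  if (any(ok)) out$p_adjusted[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out$significant <- ok & !is.na(out$p_adjusted) & out$p_adjusted <= fdr
  out$direction <- ifelse(!out$significant | is.na(out$estimate), "none",
                          ifelse(out$estimate > 0, "up", "down"))
  out
}
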