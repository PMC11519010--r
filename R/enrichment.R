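#' Test programme enrichment in inflammation
#'
#' For each programme, the response is the mean of its five per-sample
#' quantile activities. A linear mixed model with fixed effects for
#' inflammation status and clinical covariates (age, sex, site, disease
#' duration, timepoint) and a random intercept per patient is fitted with
#' `lmerTest`; if the mixed fit fails, an ordinary fixed-effects linear model
#' is used with a warning. Covariates that are constant in the data are
#' dropped automatically. Benjamini-Hochberg adjustment is applied across
#' programmes; a programme is called enriched if it is significant with a
#' positive inflammation coefficient.
#'
#' @param activity Long activity tibble from [activity_quantiles()].
#' @param sample_meta Tibble with `sample_id`, `patient_id`, `inflamed`, and
#'   the covariate columns (missing covariates are simply omitted).
#' @param covariates Candidate fixed-effect covariates.
#' @param fdr FDR threshold for the enrichment call (default 0.05).
#' @return A tibble with `gep_id`, `effect` (inflamed coefficient), `p_value`,
#'   `p_adjusted`, `enriched`, `untestable`, `model` ("lmm" or "ols").
#' @export
gep_inflammation_enrichment <- function(activity, sample_meta,
                                        covariates = c("age", "sex", "site",
                                                       "disease_duration",
                                                       "timepoint"),
                                        fdr = 0.05) {
  if (sum(sample_meta$inflamed) < 2 || sum(!sample_meta$inflamed) < 2) {
    abort("need at least 2 inflamed and 2 noninflamed samples")
  }
  resp <- activity |>
    group_by(.data$sample_id, .data$gep_id) |>
    summarise(mean_activity = mean(.data$activity), .groups = "drop") |>
    left_join(sample_meta, by = "sample_id")

  covariates <- intersect(covariates, names(sample_meta))
  fit_one <- function(df) {
    if (all(is.na(df$mean_activity)) || sd(df$mean_activity, na.rm = TRUE) == 0) {
      return(tibble(effect = 0, p_value = NA_real_, untestable = TRUE,
                    model = NA_character_))
    }
    keep_cov <- covariates[vapply(covariates, function(cv) {
      length(unique(df[[cv]][!is.na(df$mean_activity)])) > 1
    }, logical(1))]
    fixed <- paste(c("inflamed", keep_cov), collapse = " + ")
    lmm_form <- as.formula(paste("mean_activity ~", fixed, "+ (1 | patient_id)"))
    fit <- tryCatch({
      m <- suppressMessages(suppressWarnings(
        lmerTest::lmer(lmm_form, data = df)))
      cf <- stats::coef(summary(m))
      list(effect = cf["inflamedTRUE", "Estimate"],
           p = cf["inflamedTRUE", "Pr(>|t|)"],
           model = "lmm")
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warn("mixed-model fit failed; falling back to fixed-effects OLS")
      m <- lm(as.formula(paste("mean_activity ~", fixed)), data = df)
      cf <- stats::coef(summary(m))
      fit <- list(effect = cf["inflamedTRUE", "Estimate"],
                  p = cf["inflamedTRUE", "Pr(>|t|)"],
                  model = "ols")
    }
    tibble(effect = fit$effect, p_value = fit$p, untestable = FALSE,
           model = fit$model)
  }

  out <- resp |>
    dplyr::group_split(.data$gep_id) |>
    purrr::map_dfr(function(df) {
      dplyr::bind_cols(tibble(gep_id = df$gep_id[[1]]), fit_one(df))
    })
  out$p_adjusted <- NA_real_
  ok <- !out$untestable & !is.na(out$p_value)
  if (any(ok)) {
    out$p_adjusted[ok] <- p.adjust(out$p_value[ok], method = "BH")
  }
  out$enriched <- !out$untestable & !is.na(out$p_adjusted) &
    out$p_adjusted <= fdr & out$effect > 0
  out
}

#' Flag inflammatory hubs
#'
#' A hub is inflammatory if strictly more than half of its member programmes
#' are enriched in inflammation.
#'
#' @param hubs A `hub_partition` from [detect_hubs()].
#' @param enrichment Tibble from [gep_inflammation_enrichment()] covering
#'   every hub member.
#' @return The `hub_partition` with an `inflammatory` named logical vector
#'   (per hub id) and an `inflammatory` column in the assignment table.
#' @export
label_inflammatory <- function(hubs, enrichment) {
  stopifnot(inherits(hubs, "hub_partition"))
  missing_geps <- setdiff(hubs$assignment$gep_id, enrichment$gep_id)
  if (length(missing_geps) > 0) {
    abort(paste0("enrichment results missing for: ",
                 paste(missing_geps, collapse = ", ")))
  }
  joined <- hubs$assignment |>
    left_join(enrichment |> select("gep_id", "enriched"), by = "gep_id")
  per_hub <- joined |>
    group_by(.data$hub_id) |>
    summarise(frac = mean(.data$enriched), .groups = "drop")
  flags <- setNames(per_hub$frac > 0.5, per_hub$hub_id)
  hubs$inflammatory <- flags
  hubs$assignment <- joined |>
    mutate(inflammatory = unname(flags[as.character(.data$hub_id)]))
  hubs
}
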