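# Remission classification: two-of-three rules over clinical, endoscopic and
# histological indices at follow-up, with an escalation override.

#' Crohn's disease remission call
#'
#' Remission requires at least two of: HBI < 5, no macroscopic ulcers, Nancy
#' index <= 1, all at follow-up. Escalation to another advanced biologic
#' because of uncontrolled disease forces nonremission regardless of the
#' indices. All inputs are vectorised; a missing index makes the call
#' unevaluable (`NA`).
#'
#' @param hbi Harvey-Bradshaw Index (non-negative).
#' @param ulcers_present Logical, macroscopic ulcers at follow-up endoscopy.
#' @param nancy Nancy histological index (non-negative).
#' @param escalated Logical, escalation to another biologic (default `FALSE`).
#' @return Logical vector: `TRUE` remission, `FALSE` nonremission, `NA`
#'   unevaluable.
#' @export
classify_remission_cd <- function(hbi, ulcers_present, nancy,
                                  escalated = FALSE) {
  if (any(hbi < 0, na.rm = TRUE) || any(nancy < 0, na.rm = TRUE)) {
    abort("clinical indices must be non-negative")
  }
  n <- max(length(hbi), length(ulcers_present), length(nancy),
           length(escalated))
  hbi <- rep_len(hbi, n)
  ulcers_present <- rep_len(ulcers_present, n)
  nancy <- rep_len(nancy, n)
  escalated <- rep_len(escalated, n)
  met <- (hbi < 5) + (!ulcers_present) + (nancy <= 1)
  out <- met >= 2
  out[escalated %in% TRUE] <- FALSE
  out
}

#' Ulcerative colitis remission call
#'
#' Remission requires at least two of: SSCAI <= 2, UCEIS <= 1, Nancy index
#' <= 1, all at follow-up, with the same escalation override as the Crohn's
#' rule.
#'
#' @param sscai Simple Clinical Colitis Activity Index (non-negative).
#' @param uceis Ulcerative Colitis Endoscopic Index of Severity
#'   (non-negative).
#' @param nancy Nancy histological index (non-negative).
#' @param escalated Logical, escalation to another biologic (default `FALSE`).
#' @return Logical vector: `TRUE` remission, `FALSE` nonremission, `NA`
#'   unevaluable.
#' @export
classify_remission_uc <- function(sscai, uceis, nancy, escalated = FALSE) {
  if (any(sscai < 0, na.rm = TRUE) || any(uceis < 0, na.rm = TRUE) ||
      any(nancy < 0, na.rm = TRUE)) {
    abort("clinical indices must be non-negative")
  }
  n <- max(length(sscai), length(uceis), length(nancy), length(escalated))
  sscai <- rep_len(sscai, n)
  uceis <- rep_len(uceis, n)
  nancy <- rep_len(nancy, n)
  escalated <- rep_len(escalated, n)
  met <- (sscai <= 2) + (uceis <= 1) + (nancy <= 1)
  out <- met >= 2
  out[escalated %in% TRUE] <- FALSE
  out
}
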