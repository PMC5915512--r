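#' Biomarker abnormality thresholds
#'
#' Standard abnormality thresholds (amyloid-PET SUVR > 1.15, CSF p-tau >
#' 23 pg/ml) and the proposed imminent-decline thresholds (SUVR > 1.228,
#' p-tau > 45 pg/ml).
#'
#' @param suvr_standard,ptau_standard Standard abnormality thresholds.
#' @param suvr_proposed,ptau_proposed Proposed imminent-decline thresholds;
#'   each must be at least its standard counterpart.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(suvr_standard = 1.15, ptau_standard = 23,
                          suvr_proposed = 1.228, ptau_proposed = 45) {
  if (suvr_proposed < suvr_standard || ptau_proposed < ptau_standard)
    stop("proposed thresholds must be >= standard thresholds", call. = FALSE)
  structure(list(suvr_standard = suvr_standard, ptau_standard = ptau_standard,
                 suvr_proposed = suvr_proposed, ptau_proposed = ptau_proposed),
            class = "threshold_set")
}

#' Classify subjects by biomarker thresholds
#'
#' A subject is `biomarker-negative` when neither biomarker strictly exceeds
#' its standard threshold, `at-risk` when exactly one does, and
#' `preclinical` when both do. `above_proposed` flags subjects with both
#' biomarkers strictly above the proposed imminent-decline thresholds
#' (which implies `preclinical`).
#'
#' @param suvr,ptau Positive finite biomarker vectors of equal length.
#' @param thresholds A [threshold_set()].
#' @return Data frame with columns `primary` (factor with levels
#'   `biomarker-negative`, `at-risk`, `preclinical`) and `above_proposed`
#'   (logical).
#' @examples
#' classify_subject(c(1.00, 1.35), c(19.3, 56.4))
#' @export
classify_subject <- function(suvr, ptau, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"),
            length(suvr) == length(ptau))
  if (length(suvr) && (any(!is.finite(suvr)) || any(!is.finite(ptau))))
    stop("biomarker values must be finite", call. = FALSE)
  a_pos <- suvr > thresholds$suvr_standard
  t_pos <- ptau > thresholds$ptau_standard
  n_pos <- a_pos + t_pos
  primary <- factor(c("biomarker-negative", "at-risk", "preclinical")[n_pos + 1L],
                    levels = c("biomarker-negative", "at-risk", "preclinical"))
  above <- suvr > thresholds$suvr_proposed & ptau > thresholds$ptau_proposed
  data.frame(primary = primary, above_proposed = above)
}

#' Append threshold classification to a cohort
#'
#' @param cohort An `fdg_cohort` (or any data frame with
#'   `florbetapir_suvr` and `csf_ptau` columns).
#' @param thresholds A [threshold_set()].
#' @return The cohort with `primary` and `above_proposed` columns added.
#' @export
classify_cohort <- function(cohort, thresholds = threshold_set()) {
  cls <- classify_subject(cohort$florbetapir_suvr, cohort$csf_ptau, thresholds)
  cohort$primary <- cls$primary
  cohort$above_proposed <- cls$above_proposed
  cohort
}

#' Summarize threshold classification of a cohort
#'
#' @inheritParams classify_cohort
#' @return List with `counts` and `proportions` over the three primary
#'   groups, `n_above_proposed`, and the amyloid-positivity count and
#'   fraction (`suvr > suvr_standard`).
#' @export
summarize_groups <- function(cohort, thresholds = threshold_set()) {
  cls <- classify_subject(cohort$florbetapir_suvr, cohort$csf_ptau, thresholds)
  n <- nrow(cohort)
  counts <- table(cls$primary)
  list(n = n,
       counts = counts,
       proportions = if (n > 0) counts / n else counts,
       n_above_proposed = sum(cls$above_proposed),
       amyloid_positive = sum(cohort$florbetapir_suvr > thresholds$suvr_standard),
       amyloid_positive_fraction =
         if (n > 0) mean(cohort$florbetapir_suvr > thresholds$suvr_standard)
         else NA_real_)
}
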