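#' Annualized percent change in SUVR
#'
#' The change statistic used throughout:
#' \deqn{\Delta = \frac{SUVR_{fu} - SUVR_{bl}}{SUVR_{bl}} \times
#'   \frac{100}{\Delta t}}
#' with \eqn{\Delta t} the follow-up interval in years. Results are in
#' percent per year; a decline is negative.
#'
#' @param baseline,followup SUVR vectors; `baseline` must be positive.
#' @param delta_months Follow-up interval in months, positive.
#' @return Numeric vector, percent change per year.
#' @examples
#' annualized_change(1.00, 0.95, 24)  # -2.5
#' @export
annualized_change <- function(baseline, followup, delta_months) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("'baseline' must be positive and finite", call. = FALSE)
  if (any(!is.finite(delta_months)) || any(delta_months <= 0))
    stop("'delta_months' must be positive and finite", call. = FALSE)
  ((followup - baseline) / baseline) * 100 / (delta_months / 12)
}

#' Per-subject, per-ROI annualized change table
#'
#' Computes the change statistic for each subject and ROI of a cohort, plus
#' an `averaged_cluster` row per subject: the mean of the per-ROI change
#' values over `cluster_rois`.
#'
#' @param cohort An `fdg_cohort` (needs `<roi>_bl`/`<roi>_fu` columns and
#'   `followup_months`).
#' @param cluster_rois ROIs averaged into the `averaged_cluster` value;
#'   defaults to the AD-signature set.
#' @return Long data frame with columns `subject_id`, `roi`, `q_value`
#'   (percent per year).
#' @export
roi_change_table <- function(cohort, cluster_rois = ad_signature_rois()) {
  rois <- attr(cohort, "rois")
  if (is.null(rois)) {
    rois <- sub("_bl$", "", grep("_bl$", names(cohort), value = TRUE))
  }
  missing_cols <- setdiff(c(paste0(rois, "_bl"), paste0(rois, "_fu")),
                          names(cohort))
  if (length(missing_cols))
    stop("cohort is missing ROI columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_cluster <- setdiff(cluster_rois, rois)
  if (length(bad_cluster))
    stop("cluster ROIs not present in cohort: ",
         paste(bad_cluster, collapse = ", "), call. = FALSE)
  n <- nrow(cohort)
  if (n == 0L)
    return(data.frame(subject_id = character(0), roi = character(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  q <- sapply(rois, function(r) {
    bl <- cohort[[paste0(r, "_bl")]]
    fu <- cohort[[paste0(r, "_fu")]]
    if (any(!is.finite(bl)) || any(!is.finite(fu))) {
      bad <- which(!is.finite(bl) | !is.finite(fu))[1]
      stop(sprintf("missing ROI value for subject %s, ROI %s",
                   cohort$subject_id[bad], r), call. = FALSE)
    }
    annualized_change(bl, fu, cohort$followup_months)
  })
  q <- matrix(q, nrow = n, dimnames = list(NULL, rois))
  cluster <- rowMeans(q[, cluster_rois, drop = FALSE])
  out <- data.frame(
    subject_id = rep(cohort$subject_id, times = length(rois) + 1L),
    roi = rep(c(rois, "averaged_cluster"), each = n),
    q_value = c(as.vector(q), cluster),
    stringsAsFactors = FALSE)
  attr(out, "cluster_rois") <- cluster_rois
  out
}
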