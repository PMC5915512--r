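#' Construct a supra-threshold mean-change curve
#'
#' For each candidate threshold t (the sorted distinct observed biomarker
#' values), the response is the mean change statistic over all subjects
#' whose biomarker is at or above t, and `tail_count` is the size of that
#' supra-threshold group. Candidates whose tail holds fewer than `min_tail`
#' subjects are dropped, which stabilizes the right end of the curve.
#'
#' @param biomarker Per-subject biomarker values (amyloid SUVR or p-tau).
#' @param change Per-subject change statistic (percent per year).
#' @param label Axis label, e.g. `"florbetapir_suvr"`.
#' @param min_tail Minimum supra-threshold group size retained.
#' @return An object of class `threshold_curve`: a data frame with columns
#'   `threshold`, `mean_response`, `tail_count`.
#' @export
build_threshold_curve <- function(biomarker, change, label = "biomarker",
                                  min_tail = 5L) {
  stopifnot(length(biomarker) == length(change))
  if (any(!is.finite(biomarker)) || any(!is.finite(change)))
    stop("biomarker and change values must be finite", call. = FALSE)
  n <- length(biomarker)
  if (n < min_tail)
    stop(sprintf("need at least min_tail = %d subjects, got %d", min_tail, n),
         call. = FALSE)
  o <- order(biomarker)
  b <- biomarker[o]
  q <- change[o]
  tail_sums <- rev(cumsum(rev(q)))
  thresholds <- unique(b)
  first_idx <- match(thresholds, b)
  tail_count <- n - first_idx + 1L
  keep <- tail_count >= min_tail
  threshold_curve(thresholds[keep],
                  tail_sums[first_idx[keep]] / tail_count[keep],
                  tail_count[keep], label = label)
}

#' Assemble a threshold curve from precomputed values
#'
#' Low-level constructor used by [build_threshold_curve()] and available
#' directly for curves tabulated elsewhere (e.g. evaluating a known sigmoid
#' on a grid).
#'
#' @param thresholds Ascending candidate thresholds.
#' @param mean_response Supra-threshold mean change per candidate.
#' @param tail_count Supra-threshold group sizes (defaults to 1s when the
#'   curve does not arise from subject tails).
#' @param label Axis label.
#' @return A `threshold_curve`.
#' @export
threshold_curve <- function(thresholds, mean_response,
                            tail_count = rep(1L, length(thresholds)),
                            label = "biomarker") {
  stopifnot(length(thresholds) == length(mean_response),
            length(thresholds) == length(tail_count))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing", call. = FALSE)
  structure(data.frame(threshold = thresholds, mean_response = mean_response,
                       tail_count = tail_count),
            label = label, class = c("threshold_curve", "data.frame"))
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("Supra-threshold curve (%s): %d candidates over [%g, %g]\n",
              attr(x, "label"), nrow(x), min(x$threshold), max(x$threshold)))
  invisible(x)
}
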