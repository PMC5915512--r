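#' Categorize a threshold pair
#'
#' Reproduces the four-colour coding of the exhaustive threshold grid:
#' `both-below-standard` when neither candidate exceeds its standard
#' threshold, `one-above-standard` when exactly one does,
#' `above-standard-below-proposed` when both do but at least one is below
#' its proposed threshold, and `at-or-above-proposed` when both candidates
#' are at or above the proposed imminent-decline thresholds.
#'
#' @param amyloid_t,tau_t Candidate threshold vectors (recycled to a common
#'   length).
#' @param thresholds A [threshold_set()].
#' @return Factor with the four category levels.
#' @export
categorize_cell <- function(amyloid_t, tau_t, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  k <- max(length(amyloid_t), length(tau_t))
  amyloid_t <- rep_len(amyloid_t, k)
  tau_t <- rep_len(tau_t, k)
  a_std <- amyloid_t > thresholds$suvr_standard
  t_std <- tau_t > thresholds$ptau_standard
  both_prop <- amyloid_t >= thresholds$suvr_proposed &
    tau_t >= thresholds$ptau_proposed
  out <- rep("both-below-standard", k)
  out[xor(a_std, t_std)] <- "one-above-standard"
  out[a_std & t_std] <- "above-standard-below-proposed"
  out[both_prop] <- "at-or-above-proposed"
  factor(out, levels = c("both-below-standard", "one-above-standard",
                         "above-standard-below-proposed",
                         "at-or-above-proposed"))
}

#' Exhaustive two-biomarker threshold grid
#'
#' Takes every subject's observed amyloid SUVR and p-tau value as a
#' candidate threshold (n candidates per axis, n^2 cells; 120 subjects give
#' the published 14,400 combinations) and, per cell, forms the group of
#' subjects with BOTH biomarkers at or above the pair. The cell reports the
#' group size, the mean change statistic (when the group has at least
#' `min_cell` members), a two-sided one-sample t-test of the mean change
#' against zero (groups of >= 3), and the four-way category of the pair.
#'
#' @param cohort An `fdg_cohort`.
#' @param change A per-subject change vector aligned with the cohort rows,
#'   or `NULL` to use the averaged-cluster value of [roi_change_table()].
#' @param min_cell Minimum group size for reporting a mean.
#' @param thresholds A [threshold_set()] for the cell categories.
#' @param alpha Significance level for the per-cell test.
#' @return Long data frame of class `threshold_grid` with columns
#'   `amyloid_t`, `tau_t`, `group_size`, `mean_change`, `t_stat`, `p_value`,
#'   `significant`, `category`.
#' @export
build_threshold_grid <- function(cohort, change = NULL, min_cell = 3L,
                                 thresholds = threshold_set(),
                                 alpha = 0.05) {
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(change)) {
    tab <- roi_change_table(cohort)
    tab <- tab[tab$roi == "averaged_cluster", ]
    change <- tab$q_value[match(cohort$subject_id, tab$subject_id)]
  }
  stopifnot(length(change) == n)
  amyloid_c <- sort(cohort$florbetapir_suvr)
  tau_c <- sort(cohort$csf_ptau)

  suvr <- cohort$florbetapir_suvr
  ptau <- cohort$csf_ptau
  group_size <- matrix(0L, n, n)
  mean_mat <- matrix(NA_real_, n, n)
  sd_mat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    in_a <- suvr >= amyloid_c[i]
    pt <- ptau[in_a]
    qv <- change[in_a]
    o <- order(pt, decreasing = TRUE)
    pt <- pt[o]
    qv <- qv[o]
    cs <- cumsum(qv)
    cs2 <- cumsum(qv^2)
    # number of members with ptau >= tau_c[j]: pt is sorted decreasing
    cnt <- length(pt) - findInterval(tau_c, rev(pt), left.open = TRUE)
    group_size[i, ] <- cnt
    pos <- which(cnt > 0)
    mu <- rep(NA_real_, n)
    ss <- rep(NA_real_, n)
    mu[pos] <- cs[cnt[pos]] / cnt[pos]
    ok <- cnt >= 2L
    ss[ok] <- pmax(0, (cs2[cnt[ok]] - cnt[ok] * mu[ok]^2) / (cnt[ok] - 1L))
    mean_mat[i, ] <- mu
    sd_mat[i, ] <- sqrt(ss)
  }
  gs <- as.vector(group_size)
  mu <- as.vector(mean_mat)
  sdv <- as.vector(sd_mat)
  mu[gs < min_cell] <- NA_real_
  t_stat <- rep(NA_real_, length(gs))
  p_value <- rep(NA_real_, length(gs))
  testable <- gs >= 3L & !is.na(sdv) & sdv > 0
  t_stat[testable] <- mean_mat[testable] / (sdv[testable] / sqrt(gs[testable]))
  p_value[testable] <- 2 * stats::pt(abs(t_stat[testable]),
                                     gs[testable] - 1L, lower.tail = FALSE)
  out <- data.frame(
    amyloid_t = rep(amyloid_c, times = n),
    tau_t = rep(tau_c, each = n),
    group_size = gs,
    mean_change = mu,
    t_stat = t_stat,
    p_value = p_value,
    significant = !is.na(p_value) & p_value < alpha,
    category = categorize_cell(rep(amyloid_c, times = n),
                               rep(tau_c, each = n), thresholds))
  structure(out, n_subjects = n, min_cell = min_cell,
            class = c("threshold_grid", "data.frame"))
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("Threshold grid: %d cells (%d subjects per axis)\n",
              nrow(x), attr(x, "n_subjects")))
  print(table(x$category))
  invisible(x)
}
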