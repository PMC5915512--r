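#' Power-analysis parameters
#'
#' Coefficients of the per-arm sample-size formula. The defaults use the
#' conventional printed coefficients 0.842 (80% power) and 1.96 (two-sided
#' 5% significance) verbatim rather than re-derived normal quantiles, a 25%
#' drug effect, and an FDR level of 0.001 for the decline mask.
#'
#' @param power_coef Power coefficient (z for 1 - type-II error).
#' @param sig_coef Significance coefficient (z for alpha/2).
#' @param effect Fractional drug effect on the mean change, in (0, 1].
#' @param fdr_q FDR level for masking significant decline.
#' @return Object of class `power_params`.
#' @export
power_params <- function(power_coef = 0.842, sig_coef = 1.96,
                         effect = 0.25, fdr_q = 0.001) {
  if (power_coef <= 0 || sig_coef <= 0)
    stop("coefficients must be positive", call. = FALSE)
  if (effect <= 0 || effect > 1)
    stop("'effect' must lie in (0, 1]", call. = FALSE)
  if (fdr_q <= 0 || fdr_q >= 1)
    stop("'fdr_q' must lie in (0, 1)", call. = FALSE)
  structure(list(power_coef = power_coef, sig_coef = sig_coef,
                 effect = effect, fdr_q = fdr_q),
            class = "power_params")
}

#' Per-arm sample size for a change-slowing trial
#'
#' \deqn{n = \left\lceil \frac{(\partial + \delta)^2 \, 2\sigma^2}
#'   {(\Delta\mu \, \beta)^2} \right\rceil}
#' the number of subjects per arm needed to detect a fractional slowing
#' \eqn{\beta} of the mean annualized change \eqn{\Delta\mu} (entered as a
#' magnitude) against between-subject SD \eqn{\sigma}, at the stated power
#' and significance. Rounded up to the next whole subject, minimum 1.
#'
#' @param delta_mu Mean change magnitude (percent per year), positive.
#' @param sigma SD of the change (percent per year), non-negative.
#' @param params A [power_params()].
#' @return Integer vector of per-arm sample sizes.
#' @examples
#' per_arm_sample_size(3.4, 2.0)  # 87
#' @export
per_arm_sample_size <- function(delta_mu, sigma, params = power_params()) {
  stopifnot(inherits(params, "power_params"))
  if (any(!is.finite(delta_mu)) || any(delta_mu <= 0))
    stop("'delta_mu' must be positive (no decline to enrich on)",
         call. = FALSE)
  if (any(sigma < 0)) stop("'sigma' must be >= 0", call. = FALSE)
  raw <- (params$power_coef + params$sig_coef)^2 * 2 * sigma^2 /
    (delta_mu * params$effect)^2
  n <- pmax(1, ceiling(raw))
  # keep integer storage where it fits; huge unenriched designs stay numeric
  if (max(n) <= .Machine$integer.max) as.integer(n) else n
}

#' Invert the sample-size formula
#'
#' Returns the noise-to-signal ratio sigma/delta_mu at which the formula
#' yields exactly `n` (before rounding); feeding the ratio back through
#' [per_arm_sample_size()] with `delta_mu = 1` recovers `n` up to the
#' ceiling.
#'
#' @param n Per-arm sample size, >= 1.
#' @param params A [power_params()].
#' @return Numeric ratio sigma / delta_mu.
#' @export
invert_sample_size <- function(n, params = power_params()) {
  stopifnot(inherits(params, "power_params"))
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  params$effect * sqrt(n / 2) / (params$power_coef + params$sig_coef)
}

#' Voxel-wise decline statistics for one group
#'
#' Per-voxel mean, SD, and a two-sided one-sample t-test of the mean change
#' against zero across the subjects of a group. Voxels missing in any
#' subject are propagated as missing; voxels with zero variance are counted
#' and their p-value set missing.
#'
#' @param change_maps List of equally shaped arrays (one per subject), as
#'   produced by [voxel_change_map()].
#' @return List of class `voxel_stats` with arrays `mean`, `sd`, `t`, `p`,
#'   the subject count `n`, and `n_degenerate` (zero-variance voxels).
#' @export
voxel_decline_stats <- function(change_maps) {
  if (length(change_maps) < 3L)
    stop("need at least 3 subjects", call. = FALSE)
  dims <- dim(change_maps[[1]])
  if (!all(vapply(change_maps, function(m) identical(dim(m), dims),
                  logical(1))))
    stop("change maps have mismatched dimensions", call. = FALSE)
  n <- length(change_maps)
  flat <- vapply(change_maps, as.vector, numeric(prod(dims)))
  ok <- rowSums(is.na(flat)) == 0L
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1L, stats::sd)
  mu[!ok] <- NA_real_
  sdv[!ok] <- NA_real_
  tt <- mu / (sdv / sqrt(n))
  degenerate <- ok & sdv == 0
  tt[degenerate] <- NA_real_
  pp <- 2 * stats::pt(abs(tt), n - 1L, lower.tail = FALSE)
  shape <- function(v) array(v, dims)
  structure(list(mean = shape(mu), sd = shape(sdv), t = shape(tt),
                 p = shape(pp), n = n, n_degenerate = sum(degenerate)),
            class = "voxel_stats")
}

#' Benjamini-Hochberg FDR mask
#'
#' Flags the elements whose BH-adjusted p-value is below `q`; adjustment is
#' computed over the non-missing elements only and missing elements stay
#' missing in the mask.
#'
#' @param p Numeric vector or array of p-values in \[0, 1\] (NA allowed).
#' @param q FDR level in (0, 1).
#' @return Logical vector/array of the same shape.
#' @examples
#' fdr_mask(c(0.0001, 0.0005, 0.5), q = 0.001)  # TRUE TRUE FALSE
#' @export
fdr_mask <- function(p, q = 0.001) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)", call. = FALSE)
  pv <- as.vector(p)
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA, length(pv))
  ok <- !is.na(pv)
  out[ok] <- stats::p.adjust(pv[ok], method = "BH") < q
  if (!is.null(dim(p))) out <- array(out, dim(p))
  out
}

#' Per-arm sample-size map
#'
#' Applies the sample-size formula at every masked voxel using the absolute
#' mean change and SD from [voxel_decline_stats()]; unmasked or missing
#' voxels get a missing sample size. The summary reports the map minimum
#' and, when an ROI label array is supplied, per-ROI minima and medians.
#'
#' @param stats A `voxel_stats` object.
#' @param mask Logical array from [fdr_mask()] (aligned with `stats`).
#' @param params A [power_params()].
#' @param labels Optional integer ROI label array (0 = background).
#' @param roi_names Optional names for the positive labels.
#' @return Object of class `power_map`: arrays `mean_change`, `sd_change`,
#'   `p_value`, `fdr_mask`, `n_per_arm`, plus `summary`.
#' @export
sample_size_map <- function(stats, mask, params = power_params(),
                            labels = NULL, roi_names = NULL) {
  stopifnot(inherits(stats, "voxel_stats"))
  if (!identical(dim(mask), dim(stats$mean)))
    stop("mask and statistics are not aligned", call. = FALSE)
  n_map <- array(NA_real_, dim(stats$mean))
  sel <- which(!is.na(mask) & mask & !is.na(stats$mean) &
                 stats$mean != 0 & !is.na(stats$sd))
  status <- "ok"
  if (length(sel) == 0L) {
    warning("empty FDR mask: no voxel qualifies for a sample size")
    status <- "empty-mask"
  } else {
    n_map[sel] <- per_arm_sample_size(abs(stats$mean[sel]), stats$sd[sel],
                                      params)
  }
  summary <- list(status = status,
                  n_masked = length(sel),
                  min_n = if (length(sel)) min(n_map[sel]) else NA_real_)
  if (!is.null(labels) && length(sel)) {
    lab <- labels[sel]
    per_roi <- tapply(n_map[sel], lab, function(v)
      c(min = min(v), median = stats::median(v)))
    per_roi <- per_roi[names(per_roi) != "0"]
    if (!is.null(roi_names))
      names(per_roi) <- roi_names[as.integer(names(per_roi))]
    summary$per_roi <- per_roi
  }
  structure(list(mean_change = stats$mean, sd_change = stats$sd,
                 p_value = stats$p, fdr_mask = mask, n_per_arm = n_map,
                 summary = summary),
            class = "power_map")
}

#' Per-ROI, per-group power table
#'
#' For every group and ROI (including the averaged cluster), tabulates the
#' decline magnitude `delta_mu = |mean change|`, the SD of the change, and
#' the per-arm sample size from the formula. ROIs where the group mean
#' change is zero (or positive drift-free) cannot be enriched on and get a
#' missing sample size.
#'
#' @param change_table Long table from [roi_change_table()].
#' @param groups Factor/character group label per subject, named by or
#'   aligned with the distinct `subject_id`s of the table.
#' @param params A [power_params()].
#' @return Data frame with columns `group`, `roi`, `n_subjects`,
#'   `delta_mu`, `sigma`, `n_per_arm`.
#' @export
roi_power_table <- function(change_table, groups, params = power_params()) {
  ids <- unique(change_table$subject_id)
  if (length(groups) != length(ids))
    stop("'groups' must supply one label per subject", call. = FALSE)
  grp <- data.frame(subject_id = ids, group = as.character(groups),
                    stringsAsFactors = FALSE)
  merged <- merge(change_table, grp, by = "subject_id")
  pieces <- split(merged, list(merged$group, merged$roi), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    if (nrow(d) < 3L)
      stop(sprintf("group '%s' has fewer than 3 subjects", d$group[1]),
           call. = FALSE)
    mu <- mean(d$q_value)
    sdv <- stats::sd(d$q_value)
    data.frame(group = d$group[1], roi = d$roi[1], n_subjects = nrow(d),
               delta_mu = abs(mu), sigma = sdv,
               n_per_arm = if (mu == 0) NA_integer_ else
                 per_arm_sample_size(abs(mu), sdv, params),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$roi), ]
}
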