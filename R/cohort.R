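#' Region-of-interest sets
#'
#' The AD-signature regions are the clusters where a threshold-dependent
#' 2-year metabolic decline is expected (mediobasal temporal, orbitofrontal,
#' anterior and posterior cingulate cortices); the lateral temporal cortex
#' also declines but is conventionally reported separately, and the
#' precuneus and occipital clusters serve as control regions with no
#' biomarker-dependent decline.
#'
#' @return Character vector of ROI names.
#' @export
ad_signature_rois <- function() {
  c("mediobasal_temporal", "orbitofrontal", "anterior_cingulate",
    "posterior_cingulate")
}

#' @rdname ad_signature_rois
#' @export
control_rois <- function() {
  c("precuneus", "occipital")
}

#' Specify one biomarker stratum of a synthetic cohort
#'
#' A stratum is a biomarker-defined subgroup sampled from truncated normal
#' distributions. Bounds are kept a safety margin away from the
#' classification thresholds so that every sampled subject is classified
#' back into its generating stratum with certainty, regardless of seed.
#'
#' @param label Stratum name.
#' @param count Number of subjects (non-negative integer).
#' @param suvr_mean,suvr_sd Target normal moments of amyloid-PET SUVR before
#'   truncation.
#' @param suvr_bounds Length-2 numeric, admissible half-open SUVR interval.
#' @param ptau_mean,ptau_sd Target normal moments of CSF p-tau (pg/ml).
#' @param ptau_bounds Admissible p-tau interval (pg/ml).
#' @param apoe4_prob Probability of APOE-e4 carrier status.
#' @param age_mean,age_sd Age moments (years).
#' @param male_prob Probability of male sex.
#' @param educ_mean,educ_sd Education moments (years).
#' @return An object of class `stratum_spec`.
#' @export
stratum_spec <- function(label, count, suvr_mean, suvr_sd, suvr_bounds,
                         ptau_mean, ptau_sd, ptau_bounds,
                         apoe4_prob = 0.25,
                         age_mean = 74, age_sd = 6,
                         male_prob = 0.5,
                         educ_mean = 16, educ_sd = 2.5) {
  if (length(count) != 1L || is.na(count) || count < 0 || count != round(count))
    stop("'count' must be a single non-negative integer", call. = FALSE)
  if (suvr_sd <= 0 || ptau_sd <= 0)
    stop("stratum sd values must be > 0", call. = FALSE)
  if (length(suvr_bounds) != 2L || length(ptau_bounds) != 2L ||
      suvr_bounds[1] >= suvr_bounds[2] || ptau_bounds[1] >= ptau_bounds[2])
    stop("bounds must be increasing length-2 intervals", call. = FALSE)
  if (apoe4_prob < 0 || apoe4_prob > 1 || male_prob < 0 || male_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(
    list(label = label, count = as.integer(count),
         suvr_mean = suvr_mean, suvr_sd = suvr_sd, suvr_bounds = suvr_bounds,
         ptau_mean = ptau_mean, ptau_sd = ptau_sd, ptau_bounds = ptau_bounds,
         apoe4_prob = apoe4_prob, age_mean = age_mean, age_sd = age_sd,
         male_prob = male_prob, educ_mean = educ_mean, educ_sd = educ_sd),
    class = "stratum_spec")
}

#' Default cohort strata
#'
#' Five strata reproducing the published group structure of 120 cognitively
#' normal participants: 24 biomarker-negative, 63 at risk (split 3 with only
#' amyloid abnormal / 60 with only p-tau abnormal, so that exactly 36/120 =
#' 30% of subjects exceed the standard amyloid positivity threshold), 16
#' with preclinical AD below the proposed imminent-decline thresholds and 17
#' with both biomarkers above them. Biomarker moments follow the published
#' per-group means and SDs; sampling is truncated-normal with margins of
#' `margin_suvr` / `margin_ptau` around the classification thresholds.
#'
#' @param thresholds A [threshold_set()].
#' @param margin_suvr,margin_ptau Safety margins kept between stratum bounds
#'   and the classification thresholds (SUVR and pg/ml respectively).
#' @return List of [stratum_spec()] objects.
#' @export
default_strata <- function(thresholds = threshold_set(),
                           margin_suvr = 0.005, margin_ptau = 0.5) {
  t <- thresholds
  s_lo <- t$suvr_standard - margin_suvr   # upper bound for amyloid-negatives
  s_hi <- t$suvr_standard + margin_suvr   # lower bound for amyloid-positives
  s_pr <- t$suvr_proposed + margin_suvr
  p_lo <- t$ptau_standard - margin_ptau
  p_hi <- t$ptau_standard + margin_ptau
  p_be <- t$ptau_proposed - margin_ptau   # cap for below-proposed tau
  p_pr <- t$ptau_proposed + margin_ptau
  list(
    stratum_spec("biomarker_negative", 24,
                 suvr_mean = 1.00, suvr_sd = 0.03, suvr_bounds = c(0, s_lo),
                 ptau_mean = 19.3, ptau_sd = 2.9, ptau_bounds = c(0, p_lo),
                 apoe4_prob = 0.04, age_mean = 75.1, age_sd = 7.4,
                 male_prob = 0.58, educ_mean = 17.7, educ_sd = 2.5),
    stratum_spec("amyloid_only", 3,
                 suvr_mean = 1.19, suvr_sd = 0.05, suvr_bounds = c(s_hi, Inf),
                 ptau_mean = 19.3, ptau_sd = 2.9, ptau_bounds = c(0, p_lo),
                 apoe4_prob = 0.27, age_mean = 73.9, age_sd = 6.1,
                 male_prob = 0.55, educ_mean = 16.3, educ_sd = 2.9),
    stratum_spec("tau_only", 60,
                 suvr_mean = 1.12, suvr_sd = 0.10, suvr_bounds = c(0, s_lo),
                 ptau_mean = 35.8, ptau_sd = 14.8, ptau_bounds = c(p_hi, Inf),
                 apoe4_prob = 0.27, age_mean = 73.9, age_sd = 6.1,
                 male_prob = 0.55, educ_mean = 16.3, educ_sd = 2.9),
    stratum_spec("preclinical_below", 16,
                 suvr_mean = 1.25, suvr_sd = 0.08, suvr_bounds = c(s_hi, Inf),
                 ptau_mean = 36.5, ptau_sd = 8.9, ptau_bounds = c(p_hi, p_be),
                 apoe4_prob = 0.38, age_mean = 74.9, age_sd = 6.2,
                 male_prob = 0.44, educ_mean = 15.6, educ_sd = 2.4),
    stratum_spec("preclinical_above", 17,
                 suvr_mean = 1.35, suvr_sd = 0.07, suvr_bounds = c(s_pr, Inf),
                 ptau_mean = 56.4, ptau_sd = 15.8, ptau_bounds = c(p_pr, Inf),
                 apoe4_prob = 0.35, age_mean = 78.6, age_sd = 5.1,
                 male_prob = 0.42, educ_mean = 16.7, educ_sd = 2.5))
}

#' Generative decline model
#'
#' The expected annualized metabolic change of subject i in region r is
#' \deqn{Q_r = drift - M_r \, L\!\left(\frac{B_A - c_A}{d_A}\right)
#'   L\!\left(\frac{B_T - c_T}{d_T}\right)}
#' with \eqn{L} the standard logistic, \eqn{B_A} the amyloid-PET SUVR and
#' \eqn{B_T} the CSF p-tau of the subject. Control regions have
#' \eqn{M_r = 0} and decline only at the common aging drift.
#'
#' @param c_amyloid Generative amyloid inflection (SUVR).
#' @param d_amyloid Amyloid steepness (SUVR).
#' @param c_tau Generative tau inflection (pg/ml).
#' @param d_tau Tau steepness (pg/ml).
#' @param max_decline Named vector of per-ROI maximal AD decline magnitudes
#'   (percent per year).
#' @param drift Aging drift common to all ROIs (percent per year).
#' @param sigma_q Residual SD of the annualized change statistic
#'   (percent per year).
#' @return An object of class `decline_model`.
#' @export
decline_model <- function(c_amyloid = 1.228, d_amyloid = 0.02,
                          c_tau = 45, d_tau = 3.0,
                          max_decline = c(mediobasal_temporal = 3.4,
                                          orbitofrontal = 3.0,
                                          anterior_cingulate = 2.8,
                                          posterior_cingulate = 2.8,
                                          lateral_temporal = 2.5,
                                          precuneus = 0,
                                          occipital = 0),
                          drift = -0.1, sigma_q = 2.0) {
  if (d_amyloid <= 0 || d_tau <= 0)
    stop("steepness parameters must be > 0", call. = FALSE)
  if (is.null(names(max_decline)) || any(!nzchar(names(max_decline))))
    stop("'max_decline' must be a named vector of ROIs", call. = FALSE)
  if (any(max_decline < 0)) stop("'max_decline' must be >= 0", call. = FALSE)
  if (sigma_q < 0) stop("'sigma_q' must be >= 0", call. = FALSE)
  structure(
    list(c_amyloid = c_amyloid, d_amyloid = d_amyloid,
         c_tau = c_tau, d_tau = d_tau,
         max_decline = max_decline, drift = drift, sigma_q = sigma_q),
    class = "decline_model")
}

#' Expected annualized change under a decline model
#'
#' @param model A [decline_model()].
#' @param suvr,ptau Subject biomarker vectors.
#' @return Matrix (subjects x ROIs) of expected change, percent per year.
#' @export
expected_change <- function(model, suvr, ptau) {
  stopifnot(inherits(model, "decline_model"), length(suvr) == length(ptau))
  load_ <- stats::plogis((suvr - model$c_amyloid) / model$d_amyloid) *
    stats::plogis((ptau - model$c_tau) / model$d_tau)
  out <- model$drift - outer(load_, model$max_decline)
  rownames(out) <- names(suvr)
  out
}

#' Cohort generator configuration
#'
#' @param seed Integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration including this seed.
#' @param strata List of [stratum_spec()] objects.
#' @param decline A [decline_model()].
#' @param thresholds The [threshold_set()] the strata must be consistent
#'   with (used for validation only).
#' @param followup_mean,followup_sd,followup_range Follow-up interval in
#'   months: normal moments and the truncation interval.
#' @param baseline_suvr_mean,baseline_suvr_sd Per-ROI baseline FDG SUVR
#'   moments (truncated to be positive).
#' @param abeta_intercept,abeta_slope,abeta_sd CSF amyloid-beta (pg/ml) is a
#'   noisy decreasing linear transform of the amyloid-PET SUVR:
#'   `intercept + slope * SUVR + N(0, sd)`, truncated to be positive. The
#'   default noise is calibrated so the rank correlation with SUVR is about
#'   -0.65 in large cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          strata = default_strata(thresholds),
                          decline = decline_model(),
                          thresholds = threshold_set(),
                          followup_mean = 24, followup_sd = 1,
                          followup_range = c(18, 30),
                          baseline_suvr_mean = 1.30, baseline_suvr_sd = 0.08,
                          abeta_intercept = 380, abeta_slope = -180,
                          abeta_sd = 25) {
  stopifnot(inherits(decline, "decline_model"),
            inherits(thresholds, "threshold_set"))
  if (!all(vapply(strata, inherits, logical(1), "stratum_spec")))
    stop("'strata' must be a list of stratum_spec objects", call. = FALSE)
  if (abeta_slope >= 0)
    stop("'abeta_slope' must be negative (amyloid deposition lowers CSF abeta)",
         call. = FALSE)
  validate_strata(strata, thresholds)
  structure(
    list(seed = as.integer(seed), strata = strata, decline = decline,
         thresholds = thresholds,
         followup_mean = followup_mean, followup_sd = followup_sd,
         followup_range = followup_range,
         baseline_suvr_mean = baseline_suvr_mean,
         baseline_suvr_sd = baseline_suvr_sd,
         abeta_intercept = abeta_intercept, abeta_slope = abeta_slope,
         abeta_sd = abeta_sd),
    class = "cohort_config")
}

# Stratum bounds must make the classification decidable by construction:
# each biomarker interval has to sit entirely on one side of its STANDARD
# threshold (fixes the primary label), and the above-proposed flag must be
# constant over the stratum — either both intervals lie above the proposed
# pair, or at least one lies entirely at/below its proposed threshold.
validate_strata <- function(strata, thresholds) {
  for (s in strata) {
    if (s$suvr_bounds[1] < thresholds$suvr_standard &&
        s$suvr_bounds[2] > thresholds$suvr_standard)
      stop(sprintf("stratum '%s': suvr_bounds straddle the standard threshold %g",
                   s$label, thresholds$suvr_standard), call. = FALSE)
    if (s$ptau_bounds[1] < thresholds$ptau_standard &&
        s$ptau_bounds[2] > thresholds$ptau_standard)
      stop(sprintf("stratum '%s': ptau_bounds straddle the standard threshold %g",
                   s$label, thresholds$ptau_standard), call. = FALSE)
    always_above <- s$suvr_bounds[1] >= thresholds$suvr_proposed &&
      s$ptau_bounds[1] >= thresholds$ptau_proposed
    never_above <- s$suvr_bounds[2] <= thresholds$suvr_proposed ||
      s$ptau_bounds[2] <= thresholds$ptau_proposed
    if (!always_above && !never_above)
      stop(sprintf(
        "stratum '%s': above-proposed status is not decidable from its bounds",
        s$label), call. = FALSE)
  }
  invisible(TRUE)
}

# Truncated-normal sampling by rejection; bounds are assumed to hold
# non-negligible normal mass (true for all shipped strata).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  got <- 0L
  for (tries in 1:10000) {
    draw <- stats::rnorm(max(2L * (n - got), 8L), mean, sd)
    draw <- draw[draw > lower & draw < upper]
    take <- min(length(draw), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take)] <- draw[seq_len(take)]
      got <- got + take
    }
    if (got == n) return(out)
  }
  stop("rejection sampling failed: bounds carry too little normal mass",
       call. = FALSE)
}

#' Generate a seeded synthetic cohort
#'
#' Samples subjects stratum by stratum, draws demographics and biomarkers
#' from truncated normals, assigns a follow-up interval, and injects the
#' decline model multiplicatively into the longitudinal ROI panel: follow-up
#' SUVR equals `baseline * (1 + (Q + e) * dt_years / 100)` with `Q` the
#' expected annualized change and `e ~ N(0, sigma_q)`, so the annualized
#' change statistic recovers `Q + e` by construction.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `fdg_cohort`, one row per subject, with
#'   demographics, biomarkers, `followup_months`, and one
#'   `<roi>_bl`/`<roi>_fu` column pair per ROI. The configuration is kept in
#'   the `config` attribute and ROI names in the `rois` attribute.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 11))
#' nrow(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  rois <- names(config$decline$max_decline)
  rows <- lapply(config$strata, function(s) {
    n <- s$count
    if (n == 0L) return(NULL)
    data.frame(
      stratum = rep(s$label, n),
      age = stats::rnorm(n, s$age_mean, s$age_sd),
      sex = ifelse(stats::runif(n) < s$male_prob, "M", "F"),
      education = pmax(6, stats::rnorm(n, s$educ_mean, s$educ_sd)),
      apoe4 = stats::runif(n) < s$apoe4_prob,
      florbetapir_suvr = rtruncnorm(n, s$suvr_mean, s$suvr_sd,
                                    s$suvr_bounds[1], s$suvr_bounds[2]),
      csf_ptau = rtruncnorm(n, s$ptau_mean, s$ptau_sd,
                            s$ptau_bounds[1], s$ptau_bounds[2]),
      stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, rows)
  if (is.null(cohort)) {
    cohort <- data.frame(stratum = character(0), age = numeric(0),
                         sex = character(0), education = numeric(0),
                         apoe4 = logical(0), florbetapir_suvr = numeric(0),
                         csf_ptau = numeric(0), stringsAsFactors = FALSE)
  }
  n <- nrow(cohort)
  cohort <- cbind(subject_id = sprintf("S%03d", seq_len(n)), cohort,
                  stringsAsFactors = FALSE)
  cohort$csf_abeta <- pmax(
    50, config$abeta_intercept + config$abeta_slope * cohort$florbetapir_suvr +
      stats::rnorm(n, 0, config$abeta_sd))
  cohort$followup_months <- rtruncnorm(n, config$followup_mean,
                                       config$followup_sd,
                                       config$followup_range[1],
                                       config$followup_range[2])
  q_bar <- expected_change(config$decline, cohort$florbetapir_suvr,
                           cohort$csf_ptau)
  dt_years <- cohort$followup_months / 12
  for (r in rois) {
    bl <- rtruncnorm(n, config$baseline_suvr_mean, config$baseline_suvr_sd,
                     0.5, Inf)
    q_obs <- q_bar[, r] + stats::rnorm(n, 0, config$decline$sigma_q)
    cohort[[paste0(r, "_bl")]] <- bl
    cohort[[paste0(r, "_fu")]] <- bl * (1 + q_obs * dt_years / 100)
  }
  rownames(cohort) <- NULL
  structure(cohort, rois = rois, config = config,
            class = c("fdg_cohort", "data.frame"))
}

#' @export
print.fdg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic FDG cohort: %d subjects, %d ROIs (seed %d)\n",
              nrow(x), length(attr(x, "rois")), attr(x, "config")$seed))
  print(table(x$stratum))
  invisible(x)
}

#' Write / read a cohort as CSV plus a JSON configuration sidecar
#'
#' @param cohort An `fdg_cohort`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort data frame (sidecar metadata reattached when present).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  config <- attr(cohort, "config")
  sidecar <- list(seed = config$seed,
                  rois = attr(cohort, "rois"),
                  n = nrow(cohort),
                  strata = lapply(config$strata, unclass),
                  decline = unclass(config$decline),
                  thresholds = unclass(config$thresholds))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    attr(cohort, "rois") <- sidecar$rois
  } else {
    bl <- grep("_bl$", names(cohort), value = TRUE)
    attr(cohort, "rois") <- sub("_bl$", "", bl)
  }
  class(cohort) <- c("fdg_cohort", "data.frame")
  cohort
}
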