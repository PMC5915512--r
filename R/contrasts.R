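#' Covariate-adjusted group contrasts of metabolic decline
#'
#' Fits, per ROI, the ANCOVA `change ~ group + covariates` and reports every
#' pairwise group contrast (difference of adjusted group means) with its
#' standard error, raw p-value and Bonferroni-corrected p-value. The default
#' adjustment set is age, sex, education and APOE-e4 carrier status; the
#' Bonferroni family defaults to (number of ROIs) x (number of pairwise
#' contrasts) and is reported explicitly.
#'
#' @param change_table Long table from [roi_change_table()].
#' @param cohort Cohort data frame carrying the covariates, aligned by
#'   `subject_id`.
#' @param groups Factor of group labels per cohort row.
#' @param covariates Covariate column names in `cohort`.
#' @param m_tests Bonferroni family size; default `n_rois * n_pairs`.
#' @return Data frame of class `contrast_table` with columns `roi`,
#'   `group1`, `group2`, `estimate`, `se`, `t`, `p_raw`, `p_bonferroni`,
#'   plus the family size in the `m_tests` attribute.
#' @export
ancova_contrast <- function(change_table, cohort, groups,
                            covariates = c("age", "sex", "education",
                                           "apoe4"),
                            m_tests = NULL) {
  stopifnot(length(groups) == nrow(cohort))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("missing covariates: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  for (cv in covariates)
    if (anyNA(cohort[[cv]]))
      stop(sprintf("covariate '%s' has missing values", cv), call. = FALSE)
  groups <- droplevels(factor(groups))
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 3L))
    stop("every group needs at least 3 subjects", call. = FALSE)
  pairs <- utils::combn(lv, 2L)
  rois <- unique(change_table$roi)
  if (is.null(m_tests)) m_tests <- length(rois) * ncol(pairs)

  base <- cohort[, covariates, drop = FALSE]
  base$group <- groups
  base$subject_id <- cohort$subject_id
  out <- do.call(rbind, lapply(rois, function(r) {
    tab <- change_table[change_table$roi == r, ]
    d <- merge(base, tab[, c("subject_id", "q_value")], by = "subject_id")
    fml <- stats::as.formula(paste("q_value ~ group +",
                                   paste(covariates, collapse = " + ")))
    fit <- stats::lm(fml, data = d)
    if (fit$rank < length(stats::coef(fit)))
      stop(sprintf("rank-deficient design for ROI '%s'", r), call. = FALSE)
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
    df <- fit$df.residual
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      g1 <- pairs[1, k]
      g2 <- pairs[2, k]
      # contrast vector: adjusted mean(g2) - adjusted mean(g1)
      cv1 <- coef_indicator(names(beta), g1, lv)
      cv2 <- coef_indicator(names(beta), g2, lv)
      l <- cv2 - cv1
      est <- sum(l * beta)
      se <- sqrt(drop(t(l) %*% vc %*% l))
      tval <- est / se
      p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
      data.frame(roi = r, group1 = g1, group2 = g2, estimate = est, se = se,
                 t = tval, p_raw = p,
                 p_bonferroni = min(1, m_tests * p),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  structure(out, m_tests = m_tests, covariates = covariates,
            class = c("contrast_table", "data.frame"))
}

# indicator of a group level in the treatment-coded coefficient vector
coef_indicator <- function(coef_names, level, levels) {
  v <- numeric(length(coef_names))
  if (level != levels[1]) {
    idx <- match(paste0("group", level), coef_names)
    if (is.na(idx)) stop("cannot locate group coefficient", call. = FALSE)
    v[idx] <- 1
  }
  v
}

#' Per-group demographics table
#'
#' Means and SDs of continuous fields per group, and chi-squared tests
#' (without continuity correction, as appropriate for multi-category
#' tables) for categorical fields.
#'
#' @param cohort Cohort data frame.
#' @param groups Factor of group labels per row.
#' @param continuous,categorical Column names to summarize.
#' @return List with `n` per group, a `continuous` data frame (group, field,
#'   mean, sd) and a `categorical` list of per-field count tables with the
#'   chi-squared statistic and p-value.
#' @export
demographics_table <- function(cohort, groups,
                               continuous = c("age", "education",
                                              "florbetapir_suvr",
                                              "csf_ptau", "csf_abeta",
                                              "followup_months"),
                               categorical = c("sex", "apoe4")) {
  groups <- droplevels(factor(groups))
  if (nrow(cohort) == 0L || nlevels(groups) == 0L)
    stop("empty cohort or groups", call. = FALSE)
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  cont <- do.call(rbind, lapply(continuous, function(f) {
    mu <- tapply(cohort[[f]], groups, mean)
    sdv <- tapply(cohort[[f]], groups, stats::sd)
    data.frame(field = f, group = names(mu), mean = as.vector(mu),
               sd = as.vector(sdv), stringsAsFactors = FALSE)
  }))
  cat_out <- lapply(categorical, function(f) {
    v <- factor(cohort[[f]])
    if (nlevels(v) == 0L)
      stop(sprintf("categorical field '%s' has no observed levels", f),
           call. = FALSE)
    counts <- table(groups, v)
    if (nlevels(v) < 2L) {
      list(counts = counts, statistic = NA_real_, p_value = NA_real_)
    } else {
      ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
      list(counts = counts, statistic = unname(ct$statistic),
           p_value = unname(ct$p.value))
    }
  })
  names(cat_out) <- categorical
  list(n = table(groups), continuous = cont, categorical = cat_out)
}
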