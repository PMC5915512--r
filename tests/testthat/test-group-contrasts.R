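sim_contrast_data <- function(seed, effect = 0, n_per = 30L) {
  set.seed(seed)
  n <- 2L * n_per
  grp <- rep(c("ctrl", "enrich"), each = n_per)
  age <- c(rnorm(n_per, 70, 5), rnorm(n_per, 78, 5))  # deliberately imbalanced
  q <- -1 + 0.1 * (age - 74) + effect * (grp == "enrich") + rnorm(n, 0, 0.5)
  list(cohort = data.frame(subject_id = sprintf("C%03d", 1:n), age = age,
                           stringsAsFactors = FALSE),
       groups = factor(grp),
       tab = data.frame(subject_id = sprintf("C%03d", 1:n),
                        roi = "averaged_cluster", q_value = q,
                        stringsAsFactors = FALSE))
}

test_that("ANCOVA recovers an injected group effect despite age imbalance", {
  d <- sim_contrast_data(seed = 77, effect = -2)
  out <- ancova_contrast(d$tab, d$cohort, d$groups, covariates = "age",
                         m_tests = 1L)
  expect_equal(nrow(out), 1L)
  expect_lt(abs(out$estimate - (-2)), 2.5 * out$se)
  # normal-equations oracle
  X <- cbind(1, d$groups == "enrich", d$cohort$age)
  beta <- solve(crossprod(X), crossprod(X, d$tab$q_value))
  expect_equal(out$estimate, beta[2], tolerance = 1e-8)
  expect_equal(out$p_bonferroni, min(1, out$p_raw))
})

test_that("null groups give near-zero adjusted differences and calibrated p", {
  ests <- numeric(20)
  ps <- numeric(20)
  for (s in 1:20) {
    d <- sim_contrast_data(seed = 200 + s, effect = 0)
    out <- ancova_contrast(d$tab, d$cohort, d$groups, covariates = "age",
                           m_tests = 1L)
    ests[s] <- out$estimate
    ps[s] <- out$p_raw
  }
  expect_lt(abs(mean(ests)), 0.3)
  expect_lte(mean(ps < 0.05), 0.25)
})

test_that("Bonferroni uses the declared family size", {
  d <- sim_contrast_data(seed = 5, effect = -1)
  out <- ancova_contrast(d$tab, d$cohort, d$groups, covariates = "age",
                         m_tests = 12L)
  expect_equal(out$p_bonferroni, min(1, 12 * out$p_raw))
  expect_equal(attr(out, "m_tests"), 12L)
  # default family = n_rois x n_pairs
  tab2 <- rbind(d$tab, transform(d$tab, roi = "precuneus"))
  out2 <- ancova_contrast(tab2, d$cohort, d$groups, covariates = "age")
  expect_equal(attr(out2, "m_tests"), 2L)
})

test_that("contrast preconditions are enforced", {
  d <- sim_contrast_data(seed = 9)
  expect_error(ancova_contrast(d$tab, d$cohort, d$groups,
                               covariates = "weight"), "missing covariates")
  d$cohort$age[1] <- NA
  expect_error(ancova_contrast(d$tab, d$cohort, d$groups,
                               covariates = "age"), "missing values")
  tiny <- sim_contrast_data(seed = 9, n_per = 2L)
  expect_error(ancova_contrast(tiny$tab, tiny$cohort, tiny$groups,
                               covariates = "age"), "at least 3")
})

test_that("the above-proposed group declines fastest in AD ROIs only", {
  cohort <- generate_cohort(scaled_config(seed = 4L, k = 5L))
  cls <- classify_cohort(cohort)
  grp <- as.character(cls$primary)
  grp[cls$above_proposed] <- "above-proposed"
  tab <- roi_change_table(cohort)
  out <- ancova_contrast(tab[tab$roi %in% c("averaged_cluster", "precuneus"), ],
                         cohort, factor(grp))
  ad <- out[out$roi == "averaged_cluster", ]
  vs_above <- ad[ad$group1 == "above-proposed" | ad$group2 == "above-proposed", ]
  # signed difference (other - above) is positive: others decline less
  diffs <- ifelse(vs_above$group1 == "above-proposed",
                  vs_above$estimate, -vs_above$estimate)
  expect_true(all(diffs > 0))
  ctrl <- out[out$roi == "precuneus", ]
  expect_true(all(ctrl$p_bonferroni > 0.05))
})

test_that("demographics tables match hand computations", {
  g <- factor(rep(c("a", "b"), times = c(40, 60)))
  cohort <- data.frame(
    subject_id = sprintf("D%03d", 1:100),
    age = c(rep(70, 40), rep(80, 60)),
    sex = c(rep(c("M", "F"), times = c(10, 30)),
            rep(c("M", "F"), times = c(30, 30))),
    stringsAsFactors = FALSE)
  out <- demographics_table(cohort, g, continuous = "age",
                            categorical = "sex")
  expect_equal(out$continuous$mean, c(70, 80))
  # hand chi-squared without continuity correction on (10,30; 30,30)
  counts <- matrix(c(10, 30, 30, 30), 2, byrow = TRUE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat_hand <- sum((counts - expected)^2 / expected)
  expect_equal(out$categorical$sex$statistic, stat_hand, tolerance = 1e-10)
  # identical proportions: statistic 0, p = 1
  cohort2 <- cohort
  cohort2$sex <- rep(c("M", "F"), 50)  # alternating within each group
  out2 <- demographics_table(cohort2, factor(rep(c("a", "b"), each = 50)),
                             continuous = "age", categorical = "sex")
  expect_equal(out2$categorical$sex$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$categorical$sex$p_value, 1, tolerance = 1e-12)
})

test_that("generated demographics match stratum moments at scale", {
  cohort <- generate_cohort(scaled_config(seed = 13L, k = 10L))
  out <- demographics_table(cohort, factor(cohort$stratum))
  specs <- default_strata()
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  for (lab in c("biomarker_negative", "preclinical_above")) {
    s <- specs[[lab]]
    n <- s$count * 10
    row <- out$continuous[out$continuous$field == "age" &
                            out$continuous$group == lab, ]
    expect_lt(abs(row$mean - s$age_mean), 3 * s$age_sd / sqrt(n))
  }
})
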