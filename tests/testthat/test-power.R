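test_that("the per-arm formula reproduces the printed worked examples", {
  expect_equal(per_arm_sample_size(3.4, 2.0), 87L)
  expect_equal(per_arm_sample_size(1.0, 1.2867), 416L)
  expect_equal(per_arm_sample_size(1.0, 1.7138), 738L)
  # hand arithmetic: (0.842 + 1.96)^2 * 2 * 4 / (3.4 * 0.25)^2 = 86.93...
  raw <- (0.842 + 1.96)^2 * 2 * 2.0^2 / (3.4 * 0.25)^2
  expect_equal(per_arm_sample_size(3.4, 2.0), as.integer(ceiling(raw)))
})

test_that("the formula is scale invariant, floored at 1, and validated", {
  expect_equal(per_arm_sample_size(3.4, 2.0),
               per_arm_sample_size(3.4 * 2.7, 2.0 * 2.7))
  expect_equal(per_arm_sample_size(5, 0), 1L)
  expect_error(per_arm_sample_size(0, 1), "delta_mu")
  expect_error(per_arm_sample_size(-1, 1), "delta_mu")
  expect_error(per_arm_sample_size(1, -1), "sigma")
  expect_error(power_params(effect = 0), "effect")
  expect_error(power_params(fdr_q = 1), "fdr_q")
})

test_that("sample size is monotone in its arguments where unclamped", {
  base <- per_arm_sample_size(2.0, 1.5)
  expect_lt(per_arm_sample_size(2.5, 1.5), base)
  expect_gt(per_arm_sample_size(2.0, 2.0), base)
  expect_lt(per_arm_sample_size(2.0, 1.5, power_params(effect = 0.5)), base)
})

test_that("inversion roundtrips through the formula", {
  expect_equal(invert_sample_size(87), 0.25 * sqrt(87 / 2) / 2.802,
               tolerance = 1e-12)
  expect_equal(round(invert_sample_size(87), 4), 0.5885)
  for (n in c(1L, 10L, 87L, 416L, 738L)) {
    back <- per_arm_sample_size(1, invert_sample_size(n))
    expect_true(back %in% c(n, n + 1L))
  }
  expect_error(invert_sample_size(0), ">= 1")
})

test_that("computed sample sizes deliver close to the nominal 80% power", {
  params <- power_params()
  delta_mu <- 3.4
  sigma <- 2.0
  n <- per_arm_sample_size(delta_mu, sigma, params)
  set.seed(11)
  nrep <- 10000L
  placebo <- matrix(rnorm(n * nrep, -delta_mu, sigma), n)
  drug <- matrix(rnorm(n * nrep, -delta_mu * (1 - params$effect), sigma), n)
  m1 <- colMeans(placebo); m2 <- colMeans(drug)
  v1 <- colSums((placebo - rep(m1, each = n))^2) / (n - 1)
  v2 <- colSums((drug - rep(m2, each = n))^2) / (n - 1)
  se <- sqrt(v1 / n + v2 / n)
  df <- (v1 / n + v2 / n)^2 /
    ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
  p <- 2 * pt(abs(m1 - m2) / se, df, lower.tail = FALSE)
  expect_gte(mean(p < 0.05), 0.78)
  expect_lte(mean(p < 0.05), 0.84)
})

test_that("voxel statistics match per-voxel t-tests and flag degeneracy", {
  set.seed(8)
  dims <- c(6, 5, 4)
  maps <- lapply(1:6, function(i) array(rnorm(prod(dims), -1), dims))
  maps[[1]][1, 1, 1] <- NA
  st <- voxel_decline_stats(maps)
  expect_true(is.na(st$p[1, 1, 1]))
  flat <- sapply(maps, function(m) m[3, 2, 2])
  tt <- t.test(flat, mu = 0)
  expect_equal(st$t[3, 2, 2], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(st$p[3, 2, 2], tt$p.value, tolerance = 1e-10)
  # identical maps: zero variance is flagged, p missing
  same <- lapply(1:4, function(i) array(-2, c(3, 3, 3)))
  st0 <- voxel_decline_stats(same)
  expect_equal(st0$n_degenerate, 27L)
  expect_true(all(is.na(st0$p)))
  expect_error(voxel_decline_stats(same[1:2]), "at least 3")
  bad <- c(same[1:3], list(array(0, c(2, 2, 2))))
  expect_error(voxel_decline_stats(bad), "mismatch")
})

test_that("null voxel p-values are uniform and signal voxels rank first", {
  set.seed(8)
  maps <- lapply(1:10, function(i) array(rnorm(10000), c(10, 10, 100)))
  st <- voxel_decline_stats(maps)
  expect_gt(ks.test(as.vector(st$p), "punif")$p.value, 0.01)
  # inject a -3 mean at known voxels
  signal <- 1:20
  maps2 <- lapply(1:10, function(i) {
    m <- array(rnorm(10000, 0, 0.5), c(10, 10, 100))
    m[signal] <- m[signal] - 3
    m
  })
  st2 <- voxel_decline_stats(maps2)
  expect_true(all(rank(as.vector(st2$p))[signal] <= 40))
})

test_that("BH masking matches the hand computation and controls the null", {
  expect_equal(fdr_mask(c(0.0001, 0.0005, 0.5), q = 0.001),
               c(TRUE, TRUE, FALSE))
  # all equal and below q
  expect_equal(fdr_mask(rep(0.0004, 5), q = 0.001), rep(TRUE, 5))
  expect_error(fdr_mask(0.5, q = 0), "'q'")
  expect_error(fdr_mask(c(0.5, 2)), "\\[0, 1\\]")
  # missing values propagate; arrays keep their shape
  p_arr <- array(c(0.0001, NA, 0.9, 0.2), c(2, 2))
  m <- fdr_mask(p_arr, 0.01)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(is.na(m[2, 1]))
  bad_runs <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (mean(fdr_mask(runif(10000), 0.001)) > 0.001) bad_runs <- bad_runs + 1L
  }
  expect_lte(bad_runs, 5L)
})

test_that("sample-size maps apply the formula only under the mask", {
  mean_arr <- array(c(-3.4, -1.0, -0.5, 2.0), c(2, 2))
  sd_arr <- array(c(2.0, 1.7138, 1.0, 1.0), c(2, 2))
  st <- structure(list(mean = mean_arr, sd = sd_arr,
                       t = mean_arr, p = abs(mean_arr) / 10,
                       n = 5L, n_degenerate = 0L), class = "voxel_stats")
  mask <- array(c(TRUE, TRUE, FALSE, TRUE), c(2, 2))
  pm <- sample_size_map(st, mask)
  expect_equal(pm$n_per_arm[1, 1], 87)
  expect_equal(pm$n_per_arm[2, 1], 738)
  expect_true(is.na(pm$n_per_arm[1, 2]))   # unmasked
  # brute-force minimum over masked voxels
  expect_equal(pm$summary$min_n,
               min(pm$n_per_arm[mask & !is.na(pm$n_per_arm)], na.rm = TRUE))
  expect_warning(sample_size_map(st, array(FALSE, c(2, 2))), "empty")
})

test_that("enrichment shrinks the required arm on a large cohort", {
  cohort <- generate_cohort(scaled_config(seed = 44L, k = 50L))
  tab <- roi_change_table(cohort)
  tab <- tab[tab$roi == "mediobasal_temporal", ]
  cls <- classify_cohort(cohort)
  n_of <- function(keep) {
    sub <- tab[tab$subject_id %in% cohort$subject_id[keep], ]
    roi_power_table(sub, rep("g", sum(keep)))$n_per_arm
  }
  n_above <- n_of(cls$above_proposed)
  n_pre <- n_of(cls$primary == "preclinical")  # standard thresholds
  n_all <- n_of(rep(TRUE, nrow(cohort)))
  expect_lt(n_above, n_pre)
  expect_lt(n_pre, n_all)
})

test_that("ROI power tables recover known group parameters at large n", {
  set.seed(23)
  n <- 10000L
  tab <- data.frame(subject_id = sprintf("G%05d", 1:n),
                    roi = "averaged_cluster",
                    q_value = rnorm(n, -3.4, 2.0))
  out <- roi_power_table(tab, rep("enriched", n))
  analytic <- per_arm_sample_size(3.4, 2.0)
  expect_lte(abs(out$n_per_arm - analytic), 2L)
  # two identical groups produce identical rows
  tab2 <- rbind(tab, transform(tab, subject_id = paste0("H", subject_id)))
  out2 <- roi_power_table(tab2, rep(c("a", "b"), each = n))
  expect_equal(out2$n_per_arm[1], out2$n_per_arm[2])
  expect_equal(out2$delta_mu[1], out2$delta_mu[2])
  # zero-variance group floors at one subject per arm
  tab3 <- data.frame(subject_id = sprintf("Z%02d", 1:5),
                     roi = "averaged_cluster", q_value = rep(-2, 5))
  expect_equal(roi_power_table(tab3, rep("flat", 5))$n_per_arm, 1L)
  expect_error(roi_power_table(tab3[1:2, ], rep("flat", 2)), "fewer than 3")
})
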