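test_that("default cohort reproduces the published stratum structure for any seed", {
  for (seed in c(1L, 17L, 203L)) {
    cohort <- generate_cohort(cohort_config(seed = seed))
    expect_equal(nrow(cohort), 120L)
    expect_equal(as.vector(table(cohort$stratum)[c(
      "biomarker_negative", "amyloid_only", "tau_only",
      "preclinical_below", "preclinical_above")]),
      c(24L, 3L, 60L, 16L, 17L))
    # classification re-derives the generating stratum exactly
    cls <- classify_subject(cohort$florbetapir_suvr, cohort$csf_ptau)
    derived <- as.character(cls$primary)
    derived[cls$above_proposed] <- "above"
    expected <- c(biomarker_negative = "biomarker-negative",
                  amyloid_only = "at-risk", tau_only = "at-risk",
                  preclinical_below = "preclinical",
                  preclinical_above = "above")[cohort$stratum]
    expect_equal(derived, unname(expected))
  }
})

test_that("generation is deterministic and the empty cohort is valid", {
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(a, b)
  empty_strata <- lapply(default_strata(), function(s) { s$count <- 0L; s })
  empty <- generate_cohort(cohort_config(seed = 1, strata = empty_strata))
  expect_s3_class(empty, "fdg_cohort")
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("florbetapir_suvr", "csf_ptau") %in% names(empty)))
})

test_that("sampled values respect stratum bounds, margins and positivity", {
  for (seed in 1:5) {
    cohort <- generate_cohort(cohort_config(seed = seed))
    specs <- default_strata()
    names(specs) <- vapply(specs, `[[`, character(1), "label")
    for (i in seq_len(nrow(cohort))) {
      s <- specs[[cohort$stratum[i]]]
      expect_gt(cohort$florbetapir_suvr[i], s$suvr_bounds[1])
      expect_lt(cohort$florbetapir_suvr[i], s$suvr_bounds[2])
      expect_gt(cohort$csf_ptau[i], s$ptau_bounds[1])
      expect_lt(cohort$csf_ptau[i], s$ptau_bounds[2])
    }
    expect_true(all(cohort$florbetapir_suvr > 0))
    expect_true(all(cohort$csf_ptau > 0))
    expect_true(all(cohort$csf_abeta > 0))
    expect_true(all(cohort$followup_months >= 18 &
                      cohort$followup_months <= 30))
  }
})

test_that("CSF abeta is a negative rank-correlate of amyloid SUVR (|rho| near 0.68)", {
  cohort <- generate_cohort(scaled_config(seed = 7L, k = 42L))
  expect_gte(nrow(cohort), 5000L)
  rho <- cor(cohort$florbetapir_suvr, cohort$csf_abeta, method = "spearman")
  expect_lt(rho, 0)
  expect_gt(abs(rho), 0.58)
  expect_lt(abs(rho), 0.78)
})

test_that("decline is injected in AD ROIs but control ROIs only drift", {
  cohort <- generate_cohort(scaled_config(seed = 3L, k = 10L))
  tab <- roi_change_table(cohort)
  above <- cohort$subject_id[cohort$stratum == "preclinical_above"]
  model <- decline_model()
  for (roi in control_rois()) {
    q <- tab$q_value[tab$roi == roi & tab$subject_id %in% above]
    # mean equals the drift within 3 Monte-Carlo SEs
    expect_lt(abs(mean(q) - model$drift), 3 * sd(q) / sqrt(length(q)))
  }
  for (roi in c("mediobasal_temporal", "orbitofrontal")) {
    q <- tab$q_value[tab$roi == roi & tab$subject_id %in% above]
    expect_lt(mean(q), model$drift - 1)  # well below drift
  }
})

test_that("invalid stratum and model specifications are rejected", {
  expect_error(stratum_spec("x", -1, 1, 0.1, c(0, 1), 20, 2, c(0, 22)),
               "non-negative")
  expect_error(stratum_spec("x", 5, 1, 0, c(0, 1), 20, 2, c(0, 22)),
               "sd")
  bad <- default_strata()
  bad[[1]]$suvr_bounds <- c(1.0, 1.3)  # straddles the standard threshold
  expect_error(cohort_config(strata = bad), "straddle")
  bad2 <- default_strata()
  bad2[[5]]$ptau_bounds <- c(30, Inf)  # above-proposed no longer decidable
  expect_error(cohort_config(strata = bad2), "decidable")
  expect_error(decline_model(d_amyloid = 0), "steepness")
  expect_error(decline_model(sigma_q = -1), "sigma_q")
})

test_that("cohorts roundtrip through CSV plus JSON sidecar", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(cohort, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(attr(back, "rois"), attr(cohort, "rois"))
  expect_equal(back$florbetapir_suvr, cohort$florbetapir_suvr)
  expect_equal(back$mediobasal_temporal_fu, cohort$mediobasal_temporal_fu)
})
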