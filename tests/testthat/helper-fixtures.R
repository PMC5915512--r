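# Shared fixtures built in code: small cohorts, noiseless configurations,
# and a direct sigmoid sampler.

noiseless_config <- function(seed = 1L) {
  cohort_config(seed = seed, decline = decline_model(sigma_q = 0))
}

# cohort whose strata counts are all scaled by `k` (keeps the published
# 24/3/60/16/17 structure)
scaled_config <- function(seed = 1L, k = 1L, ...) {
  strata <- default_strata()
  strata <- lapply(strata, function(s) { s$count <- s$count * k; s })
  cohort_config(seed = seed, strata = strata, ...)
}

sigmoid_points <- function(a, b, c, d, from, to, n = 200L) {
  x <- seq(from, to, length.out = n)
  threshold_curve(x, evaluate_sigmoid(x, a, b, c, d))
}

# minimal hand-built table for grid tests: subject-level biomarkers + change
toy_cohort <- function(n = 10L, seed = 99L) {
  set.seed(seed)
  data.frame(subject_id = sprintf("T%02d", 1:n),
             florbetapir_suvr = runif(n, 0.9, 1.5),
             csf_ptau = runif(n, 15, 70),
             stringsAsFactors = FALSE)
}

# per-subject averaged-cluster change aligned with cohort rows
cluster_change <- function(cohort) {
  tab <- roi_change_table(cohort)
  cl <- tab[tab$roi == "averaged_cluster", ]
  cl$q_value[match(cohort$subject_id, cl$subject_id)]
}
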