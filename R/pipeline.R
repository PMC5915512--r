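#' Pipeline run configuration
#'
#' Bundles everything one seeded end-to-end run needs: the cohort
#' configuration, classification thresholds, power parameters, the ROI sets,
#' curve/grid tuning, stage toggles and an optional output directory.
#'
#' @param seed Master seed; also seeds the cohort configuration unless one
#'   is supplied.
#' @param cohort A [cohort_config()].
#' @param thresholds A [threshold_set()].
#' @param power A [power_params()].
#' @param ad_rois,ctrl_rois AD-signature and control ROI names; must exist
#'   in the cohort configuration.
#' @param min_tail Minimum supra-threshold tail for curves.
#' @param min_cell Minimum group size for grid cells.
#' @param output_dir Directory for artifacts, or `NULL` for an in-memory
#'   run.
#' @param stages Named logical vector toggling `classify`, `thresholds`,
#'   `grid`, `power`, `contrasts`, `voxel`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_config(seed = seed),
                       thresholds = threshold_set(),
                       power = power_params(),
                       ad_rois = ad_signature_rois(),
                       ctrl_rois = control_rois(),
                       min_tail = 5L, min_cell = 3L,
                       output_dir = NULL,
                       stages = c(classify = TRUE, thresholds = TRUE,
                                  grid = TRUE, power = TRUE,
                                  contrasts = TRUE, voxel = FALSE)) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(thresholds, "threshold_set"),
            inherits(power, "power_params"))
  have <- names(cohort$decline$max_decline)
  bad <- setdiff(c(ad_rois, ctrl_rois), have)
  if (length(bad))
    stop("ROIs not in the cohort configuration: ",
         paste(bad, collapse = ", "), call. = FALSE)
  defaults <- c(classify = TRUE, thresholds = TRUE, grid = TRUE,
                power = TRUE, contrasts = TRUE, voxel = FALSE)
  defaults[names(stages)] <- stages
  structure(list(seed = as.integer(seed), cohort = cohort,
                 thresholds = thresholds, power = power,
                 ad_rois = ad_rois, ctrl_rois = ctrl_rois,
                 min_tail = min_tail, min_cell = min_cell,
                 output_dir = output_dir, stages = defaults),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `thresholds` (the four threshold
#' values), `power` (the four power parameters), `min_tail`, `min_cell`,
#' `output_dir`, `stages`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "thresholds", "power", "min_tail", "min_cell",
             "output_dir", "stages")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- list(seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
  if (!is.null(raw$thresholds)) args$thresholds <-
      do.call(threshold_set, raw$thresholds)
  if (!is.null(raw$power)) args$power <- do.call(power_params, raw$power)
  for (k in c("min_tail", "min_cell", "output_dir"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$stages)) args$stages <- unlist(raw$stages)
  do.call(run_config, args)
}

# 32-bit FNV-1a over the JSON serialization of the configuration; changes
# iff the configuration content changes.
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                           digits = NA)
  bytes <- utf8ToInt(as.character(json))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # multiply mod 2^32 in two 16-bit halves to stay inside double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + (hi * prime) %% 65536 * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, classifies it, computes the change
#' table, sweeps and fits the supra-threshold curves for both biomarkers on
#' the averaged cluster, builds the exhaustive threshold grid, tabulates
#' per-group power, and runs the covariate-adjusted contrasts. Artifacts are
#' written under `config$output_dir` when set; the returned report
#' aggregates the headline numbers with the seed and a configuration hash.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-generated cohort (otherwise generated from
#'   `config$cohort`).
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 status = "ok", stages = list())
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    invisible(obj)
  }
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  report$n_subjects <- nrow(cohort)
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  run_stage <- function(name, expr) {
    if (!isTRUE(config$stages[[name]])) return(NULL)
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$status <<- "partial"
      report$stages[[name]] <<- list(status = "failed",
                                     message = conditionMessage(res))
      return(NULL)
    }
    report$stages[[name]] <<- list(status = "ok")
    res
  }

  cls <- run_stage("classify", {
    summary <- summarize_groups(cohort, config$thresholds)
    if (!is.null(out_dir)) {
      write_cohort(classify_cohort(cohort, config$thresholds),
                   file.path(out_dir, "cohort_classified.csv"))
      jsonlite::write_json(
        list(counts = as.list(summary$counts),
             n_above_proposed = summary$n_above_proposed,
             amyloid_positive_fraction = summary$amyloid_positive_fraction),
        file.path(out_dir, "classification.json"),
        auto_unbox = TRUE, digits = NA)
    }
    summary
  })
  if (!is.null(cls)) {
    report$group_counts <- as.list(cls$counts)
    report$n_above_proposed <- cls$n_above_proposed
    report$amyloid_positive_fraction <- cls$amyloid_positive_fraction
  }

  change_tab <- roi_change_table(cohort, cluster_rois = config$ad_rois)
  if (!is.null(out_dir))
    utils::write.csv(change_tab, file.path(out_dir, "change_table.csv"),
                     row.names = FALSE)
  cluster_q <- change_tab$q_value[change_tab$roi == "averaged_cluster"]
  cluster_q <- cluster_q[match(cohort$subject_id,
                               change_tab$subject_id[change_tab$roi ==
                                                       "averaged_cluster"])]

  thr <- run_stage("thresholds", {
    res <- lapply(
      list(amyloid = cohort$florbetapir_suvr, tau = cohort$csf_ptau),
      function(bio) {
        curve <- build_threshold_curve(bio, cluster_q,
                                       min_tail = config$min_tail)
        sig <- fit_sigmoid(curve)
        lin <- fit_linear(curve)
        cmp <- compare_models_aicc(lin, sig)
        est <- if (sig$converged) estimate_threshold(sig) else NULL
        list(curve = curve, sigmoid = sig, linear = lin, comparison = cmp,
             estimate = est)
      })
    if (!is.null(out_dir)) {
      for (ax in names(res))
        utils::write.csv(as.data.frame(res[[ax]]$curve),
                         file.path(out_dir, paste0("curve_", ax, ".csv")),
                         row.names = FALSE)
      jsonlite::write_json(
        lapply(res, function(r) list(
          a = r$sigmoid$a, b = r$sigmoid$b, c = r$sigmoid$c, d = r$sigmoid$d,
          r_squared = r$sigmoid$r_squared, aicc = r$sigmoid$aicc,
          preferred = r$comparison$preferred,
          prob_correct = r$comparison$prob_correct,
          threshold = r$estimate$threshold, ci95 = r$estimate$ci95)),
        file.path(out_dir, "threshold_fits.json"),
        auto_unbox = TRUE, digits = NA)
    }
    res
  })
  if (!is.null(thr))
    report$thresholds <- lapply(thr, function(r)
      list(estimate = r$estimate$threshold, ci95 = r$estimate$ci95,
           preferred_model = r$comparison$preferred,
           prob_correct = r$comparison$prob_correct))

  grid <- run_stage("grid", {
    g <- build_threshold_grid(cohort, cluster_q, min_cell = config$min_cell,
                              thresholds = config$thresholds)
    if (!is.null(out_dir))
      utils::write.csv(as.data.frame(g), file.path(out_dir, "grid.csv"),
                       row.names = FALSE)
    g
  })
  if (!is.null(grid)) report$grid_cells <- nrow(grid)

  pow <- run_stage("power", {
    cls_df <- classify_cohort(cohort, config$thresholds)
    grp <- as.character(cls_df$primary)
    grp[cls_df$above_proposed] <- "preclinical-above-proposed"
    tab <- roi_power_table(change_tab,
                           grp[match(unique(change_tab$subject_id),
                                     cohort$subject_id)],
                           config$power)
    whole <- roi_power_table(change_tab,
                             rep("whole-cohort", nrow(cohort)), config$power)
    tab <- rbind(tab, whole)
    if (!is.null(out_dir))
      utils::write.csv(tab, file.path(out_dir, "power_table.csv"),
                       row.names = FALSE)
    tab
  })
  if (!is.null(pow)) {
    key <- pow[pow$roi == "averaged_cluster", ]
    report$per_arm_sample_size <-
      stats::setNames(as.list(key$n_per_arm), key$group)
  }

  if (isTRUE(config$stages[["voxel"]])) {
    vox <- run_stage("voxel", {
      img <- image_config(rois = attr(cohort, "rois"))
      cls_df <- classify_cohort(cohort, config$thresholds)
      sel <- which(cls_df$above_proposed)
      pairs <- generate_volume_pairs(cohort, img,
                                     subjects = cohort$subject_id[sel],
                                     seed = config$seed)
      maps <- lapply(pairs, voxel_change_map)
      vstats <- voxel_decline_stats(maps)
      mask <- fdr_mask(vstats$p, config$power$fdr_q)
      pmap <- sample_size_map(vstats, mask, config$power,
                              labels = img$labels, roi_names = img$rois)
      if (!is.null(out_dir)) {
        RNifti::writeNifti(RNifti::asNifti(pmap$mean_change),
                           file.path(out_dir, "voxel_mean_change.nii.gz"))
        nmap <- pmap$n_per_arm
        RNifti::writeNifti(RNifti::asNifti(nmap),
                           file.path(out_dir, "voxel_n_per_arm.nii.gz"))
      }
      pmap$summary
    })
    if (!is.null(report$stages$voxel) &&
        identical(report$stages$voxel$status, "ok"))
      report$voxel <- list(min_n = vox$min_n, n_masked = vox$n_masked)
  }

  run_stage("contrasts", {
    cls_df <- classify_cohort(cohort, config$thresholds)
    grp <- as.character(cls_df$primary)
    grp[cls_df$above_proposed] <- "preclinical-above-proposed"
    ct <- ancova_contrast(change_tab, cohort, grp)
    if (!is.null(out_dir))
      utils::write.csv(as.data.frame(ct),
                       file.path(out_dir, "contrasts.csv"),
                       row.names = FALSE)
    ct
  })

  class(report) <- "pipeline_report"
  if (!is.null(out_dir))
    write_report(report, file.path(out_dir, "report.json"))
  report
}

#' Serialize a pipeline report as JSON
#'
#' Floats are written at full precision. The document always carries
#' `seed`, `config_hash` and `status` fields; an empty stage list is valid.
#'
#' @param report A `pipeline_report` (or plain list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  required <- c("seed", "status")
  for (f in required)
    if (is.null(report[[f]]))
      stop(sprintf("report lacks required field '%s'", f), call. = FALSE)
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d, config %s): %s\n",
              x$seed, x$config_hash, x$status))
  if (!is.null(x$thresholds))
    for (ax in names(x$thresholds))
      cat(sprintf("  %s threshold: %.4g\n", ax, x$thresholds[[ax]]$estimate))
  if (!is.null(x$per_arm_sample_size)) {
    cat("  per-arm n (averaged cluster):\n")
    for (g in names(x$per_arm_sample_size))
      cat(sprintf("    %s: %s\n", g, x$per_arm_sample_size[[g]]))
  }
  invisible(x)
}
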