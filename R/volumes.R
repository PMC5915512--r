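#' Synthetic image-grid configuration
#'
#' A voxel-wise stand-in for preprocessed PET maps: each ROI is a box in a
#' small 3-D grid and the remaining voxels are background (label 0). Boxes
#' are laid out as non-overlapping slabs so every labelled voxel belongs to
#' exactly one ROI.
#'
#' @param rois ROI names to lay out.
#' @param dim Grid dimensions, default 32 x 32 x 32.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param noise_sd Voxel noise SD added around the ROI panel value (SUVR
#'   units).
#' @param background Background voxel intensity (SUVR-like, carries no
#'   change).
#' @return Object of class `image_config` with a `labels` array.
#' @export
image_config <- function(rois = names(decline_model()$max_decline),
                         dim = c(32L, 32L, 32L), voxel_size_mm = 4,
                         noise_sd = 0.01, background = 1.0) {
  stopifnot(length(dim) == 3L, all(dim >= 4L))
  labels <- array(0L, dim)
  n_roi <- length(rois)
  # stack ROI boxes along z, inset by one voxel in x/y
  z_edges <- round(seq(1, dim[3] + 1, length.out = n_roi + 1L))
  for (i in seq_len(n_roi)) {
    z0 <- z_edges[i]
    z1 <- z_edges[i + 1L] - 1L
    if (z1 < z0) stop("grid too small for the requested ROIs", call. = FALSE)
    labels[2:(dim[1] - 1L), 2:(dim[2] - 1L), z0:z1] <- i
  }
  structure(list(dim = dim, voxel_size_mm = voxel_size_mm,
                 noise_sd = noise_sd, background = background,
                 rois = rois, labels = labels),
            class = "image_config")
}

#' Generate paired baseline/follow-up volumes for a cohort
#'
#' Each subject's volumes encode the ROI panel: baseline voxels inside an
#' ROI mask are the panel baseline SUVR plus voxel noise, and follow-up
#' voxels the panel follow-up SUVR plus noise, so the ROI mean of the
#' voxel-wise change map agrees with the tabular change statistic up to
#' voxel noise.
#'
#' @param cohort An `fdg_cohort`.
#' @param config An [image_config()]; its ROIs must exist in the cohort
#'   panel and every ROI mask must be nonempty.
#' @param subjects Optional subset of subject ids.
#' @param seed RNG seed for the voxel noise.
#' @return List of `volume_pair` objects (fields `subject_id`, `baseline`,
#'   `followup`, `labels`, `voxel_size_mm`, `rois`, `followup_months`).
#' @export
generate_volume_pairs <- function(cohort, config = image_config(),
                                  subjects = NULL, seed = 1L) {
  stopifnot(inherits(config, "image_config"))
  rois <- config$rois
  missing_rois <- setdiff(c(paste0(rois, "_bl"), paste0(rois, "_fu")),
                          names(cohort))
  if (length(missing_rois))
    stop("cohort lacks ROI columns: ", paste(missing_rois, collapse = ", "),
         call. = FALSE)
  for (i in seq_along(rois))
    if (!any(config$labels == i))
      stop(sprintf("ROI '%s' has an empty mask", rois[i]), call. = FALSE)
  if (is.null(subjects)) subjects <- cohort$subject_id
  rows <- match(subjects, cohort$subject_id)
  if (anyNA(rows)) stop("unknown subject id", call. = FALSE)
  set.seed(seed)
  lapply(rows, function(r) {
    bl <- array(config$background, config$dim)
    fu <- array(config$background, config$dim)
    for (i in seq_along(rois)) {
      vox <- which(config$labels == i)
      bl[vox] <- cohort[[paste0(rois[i], "_bl")]][r]
      fu[vox] <- cohort[[paste0(rois[i], "_fu")]][r]
    }
    if (config$noise_sd > 0) {
      bl <- bl + array(stats::rnorm(prod(config$dim), 0, config$noise_sd),
                       config$dim)
      fu <- fu + array(stats::rnorm(prod(config$dim), 0, config$noise_sd),
                       config$dim)
    }
    structure(list(subject_id = cohort$subject_id[r], baseline = bl,
                   followup = fu, labels = config$labels,
                   voxel_size_mm = config$voxel_size_mm, rois = rois,
                   followup_months = cohort$followup_months[r]),
              class = "volume_pair")
  })
}

#' Voxel-wise annualized change map
#'
#' Applies [annualized_change()] at every labelled voxel. Background voxels
#' (label 0) are set missing, never zero, since zero is a legal change
#' value. Labelled voxels with a non-positive baseline are counted in the
#' `n_flagged` attribute and set missing.
#'
#' @param pair A `volume_pair`.
#' @param delta_months Follow-up interval in months; defaults to the pair's
#'   own interval.
#' @return 3-D array of percent change per year with attribute `n_flagged`.
#' @export
voxel_change_map <- function(pair, delta_months = pair$followup_months) {
  stopifnot(inherits(pair, "volume_pair"))
  if (!identical(dim(pair$baseline), dim(pair$followup)) ||
      !identical(dim(pair$baseline), dim(pair$labels)))
    stop("volume dimensions do not match", call. = FALSE)
  if (length(delta_months) != 1L || !is.finite(delta_months) ||
      delta_months <= 0)
    stop("'delta_months' must be a single positive number", call. = FALSE)
  out <- array(NA_real_, dim(pair$baseline))
  inside <- pair$labels > 0L
  bad <- inside & pair$baseline <= 0
  use <- inside & !bad
  out[use] <- ((pair$followup[use] - pair$baseline[use]) /
                 pair$baseline[use]) * 100 / (delta_months / 12)
  attr(out, "n_flagged") <- sum(bad)
  out
}

#' Mean of a volume over each ROI label
#'
#' @param volume 3-D array.
#' @param labels Integer label array (0 = background, excluded).
#' @param roi_names Optional names for the positive labels.
#' @return Named numeric vector of ROI means.
#' @export
roi_volume_means <- function(volume, labels, roi_names = NULL) {
  if (!identical(dim(volume), dim(labels)))
    stop("volume and labels do not match", call. = FALSE)
  pos <- labels > 0L
  means <- tapply(volume[pos], labels[pos], mean, na.rm = TRUE)
  if (!is.null(roi_names)) names(means) <- roi_names[as.integer(names(means))]
  means
}

#' Write a volume pair (plus labels) as NIfTI-1
#'
#' @param pair A `volume_pair`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_volume_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "volume_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- rep(pair$voxel_size_mm, 3)
  paths <- file.path(dir, paste0(pair$subject_id,
                                 c("_baseline.nii.gz", "_followup.nii.gz",
                                   "_labels.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(pair$baseline, pixdim = ps), paths[1])
  RNifti::writeNifti(RNifti::asNifti(pair$followup, pixdim = ps), paths[2])
  RNifti::writeNifti(RNifti::asNifti(pair$labels, pixdim = ps), paths[3])
  invisible(paths)
}
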