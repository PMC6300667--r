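# S3 containers for subject-level data and simulation ground truth.

#' Construct a SubjectDataset
#'
#' Holds one subject's masked voxel time series together with the scan
#' geometry needed downstream: repetition time, per-voxel mm coordinates,
#' hemisphere labels, and (optionally) measured nuisance series.
#'
#' @param voxel_series numeric matrix, voxels x time.
#' @param tr_seconds repetition time in seconds.
#' @param voxel_coords_mm numeric voxels x 3 matrix of mm coordinates.
#' @param hemisphere character per-voxel `"L"`/`"R"`.
#' @param subject_id label.
#' @param mask_id label for the voxel mask.
#' @param nuisance optional list with `motion` (time x 6), `ventricle`
#'   (length-time), `white_matter` (length-time).
#' @return object of class `subject_dataset`.
#' @export
subject_dataset <- function(voxel_series, tr_seconds, voxel_coords_mm,
                            hemisphere, subject_id, mask_id = "pulvinar",
                            nuisance = NULL) {
  voxel_series <- as.matrix(voxel_series)
  voxel_coords_mm <- as.matrix(voxel_coords_mm)
  stopifnot(nrow(voxel_series) == nrow(voxel_coords_mm),
            ncol(voxel_coords_mm) == 3,
            length(hemisphere) == nrow(voxel_series),
            tr_seconds > 0)
  if (anyNA(voxel_series)) stop("subject_dataset: missing samples in voxel_series")
  if (anyDuplicated(voxel_coords_mm)) {
    stop("subject_dataset: voxel coordinates must be unique")
  }
  structure(
    list(voxel_series = voxel_series, tr_seconds = tr_seconds,
         voxel_coords_mm = voxel_coords_mm, hemisphere = hemisphere,
         subject_id = subject_id, mask_id = mask_id, nuisance = nuisance),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("SubjectDataset '%s' [%s]: %d voxels x %d timepoints, TR %.2fs\n",
              x$subject_id, x$mask_id, nrow(x$voxel_series),
              ncol(x$voxel_series), x$tr_seconds))
  invisible(x)
}

#' Number of timepoints in a subject dataset
#' @param x a `subject_dataset`.
#' @export
n_timepoints <- function(x) ncol(x$voxel_series)

#' Construct a SimulationTruth record
#'
#' Ground-truth labels planted by the generators, consumed by recovery
#' tests: network membership per area, each voxel's position on the planted
#' topographic gradient, temporal-receptive-window labels, planted GLM
#' effect sizes, and the planted peak voxel per area.
#'
#' @param network_assignment named character vector, area -> network.
#' @param voxel_gradient data frame with per-voxel `hemisphere`,
#'   `compartment`, `gradient`.
#' @param trw_label named character vector region -> `"short"`/`"long"`, or NULL.
#' @param planted_betas matrix voxels x conditions, or NULL.
#' @param planted_peak data frame area/hemisphere/x/y/z/voxel, or NULL.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(network_assignment, voxel_gradient = NULL,
                      trw_label = NULL, planted_betas = NULL,
                      planted_peak = NULL) {
  structure(
    list(network_assignment = network_assignment,
         voxel_gradient = voxel_gradient, trw_label = trw_label,
         planted_betas = planted_betas, planted_peak = planted_peak),
    class = "sim_truth"
  )
}
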