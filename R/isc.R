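# Inter-subject correlation (ISC) and the intact-vs-scrambled timescale
# contrast. ISC indexes stimulus-locked, stereotyped processing: each
# subject's response is correlated with the average of all other subjects;
# regions with long temporal receptive windows lose consistency when the
# movie's segments are reordered, short-window regions do not.

#' Average stimulus repetitions within subject
#'
#' @param runs list of equal-shaped voxels x time matrices (or vectors).
#' @return pointwise mean, same shape as each run.
#' @export
average_repetitions <- function(runs) {
  stopifnot(length(runs) >= 1)
  dims <- lapply(runs, function(r) dim(as.matrix(r)))
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1) {
    stop("average_repetitions: repetitions differ in shape")
  }
  out <- Reduce(`+`, lapply(runs, as.matrix)) / length(runs)
  if (is.null(dim(runs[[1]]))) as.numeric(out) else out
}

#' Leave-one-out inter-subject correlation
#'
#' Per voxel, `r_i = cor(subject i, mean of the other subjects)`; the map
#' value is the arithmetic mean of the `r_i`. Subjects with a zero-variance
#' series at a voxel are excluded from that voxel's summary (and noted).
#'
#' @param per_subject list of voxels x time matrices (one per subject),
#'   common voxel set and time axis.
#' @return object of class `isc_map`: list with `r` (per-voxel mean ISC),
#'   `r_subject` (voxels x subjects), `n_subjects`.
#' @export
leave_one_out_isc <- function(per_subject) {
  n <- length(per_subject)
  if (n < 2) stop("leave_one_out_isc: need at least 2 subjects")
  mats <- lapply(per_subject, as.matrix)
  nv <- nrow(mats[[1]])
  total <- Reduce(`+`, mats)
  rs <- sapply(seq_len(n), function(i) {
    others <- (total - mats[[i]]) / (n - 1)
    vapply(seq_len(nv), function(v) safe_cor(mats[[i]][v, ], others[v, ]),
           numeric(1))
  })
  if (is.null(dim(rs))) rs <- matrix(rs, nrow = nv)
  if (anyNA(rs)) pv_log("leave_one_out_isc: zero-variance series excluded from summary")
  structure(list(r = rowMeans(rs, na.rm = TRUE), r_subject = rs,
                 n_subjects = n),
            class = "isc_map")
}

#' Intact vs scrambled ISC timescale contrast
#'
#' Labels voxels as `consistent` (mean intact ISC above `threshold`) and as
#' `long_timescale` (intact minus scrambled ISC above `threshold`).
#'
#' @param isc_intact,isc_scrambled `isc_map`s over the same voxel set.
#' @param threshold labeling threshold (default 0.15).
#' @return list with `difference`, `consistent`, `long_timescale`,
#'   `threshold`.
#' @export
isc_timescale_contrast <- function(isc_intact, isc_scrambled, threshold = 0.15) {
  if (length(isc_intact$r) != length(isc_scrambled$r)) {
    stop("isc_timescale_contrast: condition maps cover different voxel sets")
  }
  diff <- isc_intact$r - isc_scrambled$r
  list(difference = diff,
       consistent = isc_intact$r > threshold,
       long_timescale = diff > threshold,
       threshold = threshold)
}

#' Run the full ISC analysis on a simulated movie dataset
#'
#' Averages repetitions within subject per condition, computes leave-one-
#' out ISC per region and condition, and forms the timescale contrast.
#'
#' @param movie a `movie_dataset` from [generate_movie_dataset()].
#' @param threshold labeling threshold (default 0.15).
#' @return list per region with `isc_intact`, `isc_scrambled`,
#'   `mean_intact`, `mean_scrambled`, `difference` (means over voxels) and
#'   the voxelwise `contrast`.
#' @export
isc_analysis <- function(movie, threshold = 0.15) {
  regions <- names(movie$trw_spec)
  out <- lapply(regions, function(rg) {
    per_cond <- lapply(c(intact = "intact", scrambled = "scrambled"), function(cond) {
      lapply(seq_len(movie$n_subjects), function(s) {
        average_repetitions(movie$responses[[cond]][[s]][[rg]])
      })
    })
    ii <- leave_one_out_isc(per_cond$intact)
    ss <- leave_one_out_isc(per_cond$scrambled)
    list(isc_intact = ii, isc_scrambled = ss,
         mean_intact = mean(ii$r), mean_scrambled = mean(ss$r),
         difference = mean(ii$r) - mean(ss$r),
         contrast = isc_timescale_contrast(ii, ss, threshold))
  })
  stats::setNames(out, regions)
}
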