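# The two-step Pearson correlation ("connectivity fingerprint") analysis.
#
# Step 1, per subject: temporal correlations between every pair of
# cortical area mean series (the cortical area correlation profile) and
# between every area series and every thalamic voxel series (the voxel's
# cortical correlation profile). Step 2: each voxel's profile is
# correlated with the leave-that-subject-out pseudo-group average profile
# of each cortical area, yielding one voxel map of second-order profile
# similarity per area per subject — the pulvino-cortical connectivity.
# Correlations are within-hemisphere by default.

#' Cortical area correlation profile of one subject
#'
#' @param area_series areas x time matrix (one hemisphere's areas).
#' @return symmetric Pearson matrix with unit diagonal.
#' @export
area_profile <- function(area_series) {
  area_series <- as.matrix(area_series)
  if (ncol(area_series) < 3) stop("area_profile: need at least 3 timepoints")
  sds <- apply(area_series, 1, stats::sd)
  if (any(sds == 0)) {
    stop("area_profile: constant series for area(s): ",
         paste(rownames(area_series)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(area_series))
  dimnames(r) <- list(rownames(area_series), rownames(area_series))
  r
}

#' Voxelwise cortical correlation profiles
#'
#' Pearson correlation of every thalamic voxel series with every cortical
#' area mean series.
#'
#' @param voxel_series voxels x time matrix.
#' @param area_series areas x time matrix (same time axis).
#' @return voxels x areas correlation matrix.
#' @export
voxel_profiles <- function(voxel_series, area_series) {
  voxel_series <- as.matrix(voxel_series)
  area_series <- as.matrix(area_series)
  stopifnot(ncol(voxel_series) == ncol(area_series))
  sds <- apply(area_series, 1, stats::sd)
  if (any(sds == 0)) {
    stop("voxel_profiles: constant series for area(s): ",
         paste(rownames(area_series)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(voxel_series), t(area_series))
  colnames(r) <- rownames(area_series)
  r
}

#' Leave-one-subject-out pseudo-group correlation profile
#'
#' Entrywise Fisher-z average of the included subjects' area correlation
#' profiles, transformed back to r. The excluded subject contributes
#' nothing, so its own data never enter its reference profile.
#'
#' @param profiles list of area x area correlation matrices, one per subject.
#' @param exclude_subject index to leave out (NULL for the full group).
#' @return pseudo-group correlation profile matrix.
#' @export
pseudo_group_profile <- function(profiles, exclude_subject = NULL) {
  keep <- seq_along(profiles)
  if (!is.null(exclude_subject)) keep <- setdiff(keep, exclude_subject)
  if (!length(keep)) stop("pseudo_group_profile: exclusion leaves no subjects")
  zs <- lapply(profiles[keep], function(p) {
    z <- fisher_z(p)
    diag(z) <- 0   # diagonal is identically 1; excluded from averaging space
    z
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  out <- fisher_z_inv(zbar)
  diag(out) <- 1
  dimnames(out) <- dimnames(profiles[[1]])
  out
}

#' Second-order profile similarity map
#'
#' For each cortical area, correlates every voxel's cortical correlation
#' profile with that area's (pseudo-group) profile. By default the seed
#' area's own entry is excluded from both vectors (the area side would be
#' identically 1); set `include_self = TRUE` for the variant that keeps it.
#'
#' @param vox_prof voxels x areas matrix from [voxel_profiles()].
#' @param group_prof areas x areas pseudo-group profile (same area order).
#' @param include_self keep the seed area's self-entry (default FALSE).
#' @return voxels x areas matrix of profile similarities in `[-1, 1]`;
#'   voxels with a degenerate (constant) profile vector are NA.
#' @export
profile_similarity_map <- function(vox_prof, group_prof, include_self = FALSE) {
  vox_prof <- as.matrix(vox_prof)
  group_prof <- as.matrix(group_prof)
  n_area <- ncol(vox_prof)
  stopifnot(nrow(group_prof) == n_area, ncol(group_prof) == n_area)
  if (!is.null(colnames(vox_prof)) && !is.null(colnames(group_prof)) &&
      !identical(colnames(vox_prof), colnames(group_prof))) {
    stop("profile_similarity_map: area ordering differs between inputs")
  }
  out <- matrix(NA_real_, nrow(vox_prof), n_area,
                dimnames = list(NULL, colnames(group_prof)))
  for (a in seq_len(n_area)) {
    cols <- if (include_self) seq_len(n_area) else setdiff(seq_len(n_area), a)
    v <- vox_prof[, cols, drop = FALSE]
    g <- group_prof[a, cols]
    v0 <- v - rowMeans(v)
    g0 <- g - mean(g)
    den <- sqrt(rowSums(v0^2)) * sqrt(sum(g0^2))
    r <- as.numeric(v0 %*% g0) / den
    r[den == 0] <- NA_real_
    out[, a] <- r
  }
  if (anyNA(out)) pv_log("profile_similarity_map: degenerate profiles masked out")
  out
}

#' Run the full two-step connectivity analysis on a resting dataset
#'
#' Per hemisphere: computes each subject's area profile and voxel
#' profiles, the leave-one-out pseudo-group area profiles, and each
#' subject's per-area voxel similarity maps; then group statistics.
#'
#' @param rest a (preprocessed) `rest_dataset`.
#' @param include_self see [profile_similarity_map()].
#' @param cross_hemisphere if TRUE, profiles use both hemispheres' areas
#'   (default FALSE: within-hemisphere only).
#' @return object of class `connectivity_maps`: per hemisphere a list with
#'   `subject_maps` (list of voxels x areas), `group` (from
#'   [group_connectivity()]), `voxel_coords`, `area_names`.
#' @export
connectivity_analysis <- function(rest, include_self = FALSE,
                                  cross_hemisphere = FALSE) {
  hemis <- rest$areas$hemispheres
  n_sub <- length(rest$subjects)
  out <- list()
  for (h in hemis) {
    a_idx <- if (cross_hemisphere) seq_along(rest$areas$name) else area_hemi_idx(rest$areas, h)
    v_sel <- rest$subjects[[1]]$hemisphere == h
    profiles <- lapply(seq_len(n_sub), function(s) {
      area_profile(rest$areas$series[[s]][a_idx, , drop = FALSE])
    })
    vox_prof <- lapply(seq_len(n_sub), function(s) {
      voxel_profiles(rest$subjects[[s]]$voxel_series[v_sel, , drop = FALSE],
                     rest$areas$series[[s]][a_idx, , drop = FALSE])
    })
    subject_maps <- lapply(seq_len(n_sub), function(s) {
      pgp <- pseudo_group_profile(profiles, exclude_subject = s)
      profile_similarity_map(vox_prof[[s]], pgp, include_self = include_self)
    })
    out[[h]] <- list(
      subject_maps = subject_maps,
      group = group_connectivity(subject_maps),
      voxel_coords = rest$subjects[[1]]$voxel_coords_mm[v_sel, , drop = FALSE],
      area_names = rest$areas$name[a_idx]
    )
  }
  structure(out, class = "connectivity_maps",
            hemispheres = hemis, n_subjects = n_sub)
}

#' Group-level connectivity maps
#'
#' Fisher-z transforms each subject's similarity maps, averages (mean map
#' reported back in r units), and runs voxelwise one-sample two-tailed t
#' tests with BH-FDR adjustment per area map.
#'
#' @param subject_maps list of voxels x areas matrices.
#' @return list with `mean`, `t`, `p`, `q` (all voxels x areas), `n`.
#' @export
group_connectivity <- function(subject_maps) {
  n <- length(subject_maps)
  if (n < 2) stop("group_connectivity: need at least 2 subjects")
  zs <- lapply(subject_maps, fisher_z)
  zbar <- Reduce(`+`, zs) / n
  zsd <- sqrt(Reduce(`+`, lapply(zs, function(z) (z - zbar)^2)) / (n - 1))
  tmap <- zbar / (zsd / sqrt(n))
  tmap[zsd == 0] <- NA_real_
  pmap <- 2 * stats::pt(-abs(tmap), n - 1)
  qmap <- pmap
  qmap[] <- NA_real_
  for (j in seq_len(ncol(pmap))) {
    ok <- !is.na(pmap[, j])
    qmap[ok, j] <- stats::p.adjust(pmap[ok, j], method = "BH")
  }
  list(mean = fisher_z_inv(zbar), t = tmap, p = pmap, q = qmap, n = n)
}

#' Split-half reliability of group connectivity maps
#'
#' Repeatedly splits subjects into random halves, averages each half's
#' maps (Fisher-z space) and correlates the two half-group maps spatially
#' per area; reports the mean and SD over iterations of the across-area
#' mean correlation. Odd subject counts give unbalanced halves.
#'
#' @param subject_maps list of voxels x areas matrices.
#' @param iterations number of random splits (default 500).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `per_iteration`, `per_area` (mean r per
#'   area across iterations).
#' @export
split_half_reliability <- function(subject_maps, iterations = 500, seed = 1L) {
  n <- length(subject_maps)
  if (n < 4) stop("split_half_reliability: need at least 4 subjects")
  zs <- lapply(subject_maps, fisher_z)
  n_area <- ncol(zs[[1]])
  with_seed(substream_seed(seed, "split-half"), {
    vals <- matrix(NA_real_, iterations, n_area)
    for (it in seq_len(iterations)) {
      half <- sample.int(n, floor(n / 2))
      m1 <- Reduce(`+`, zs[half]) / length(half)
      m2 <- Reduce(`+`, zs[-half]) / (n - length(half))
      vals[it, ] <- vapply(seq_len(n_area),
                           function(a) safe_cor(m1[, a], m2[, a]), numeric(1))
    }
    per_it <- rowMeans(vals, na.rm = TRUE)
    list(mean = mean(per_it), sd = stats::sd(per_it), per_iteration = per_it,
         per_area = colMeans(vals, na.rm = TRUE))
  })
}
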