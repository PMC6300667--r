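# Time-series conditioning applied before correlation analyses:
# (1) despike, (2) band-pass 0.01-0.1 Hz, (3) linear+quadratic detrend,
# (4) nuisance regression (motion + derivatives, ventricle, white matter;
# no global-mean removal), initial-sample removal, and within-mask spatial
# smoothing of thalamic data.

#' Despike a time series by clipping extreme deviations
#'
#' Samples deviating more than `threshold_sd` SDs from the series mean are
#' clipped to the mean +/- `threshold_sd` * SD envelope (mean and SD taken
#' from the original series); all other samples are unchanged.
#'
#' @param series numeric vector (or voxels x time matrix; applied rowwise).
#' @param threshold_sd deviation threshold in SD units (default 2.5).
#' @return despiked series, same shape.
#' @export
despike <- function(series, threshold_sd = 2.5) {
  if (is.matrix(series)) {
    return(t(apply(series, 1, despike, threshold_sd = threshold_sd)))
  }
  if (length(series) < 3) stop("despike: series too short")
  m <- mean(series)
  s <- stats::sd(series)
  if (s == 0) {
    pv_log("despike: zero-variance series returned unchanged")
    return(series)
  }
  pmin(pmax(series, m - threshold_sd * s), m + threshold_sd * s)
}

#' Band-pass filter a time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass retaining
#' `low`-`high` Hz; the mean is removed. Effective amplitude response is
#' the squared magnitude of a 4th-order Butterworth band-pass.
#'
#' @param series numeric vector or voxels x time matrix (rowwise).
#' @param low,high band edges in Hz (defaults 0.01 and 0.1).
#' @param tr_seconds sampling interval in seconds.
#' @param order filter order (default 4).
#' @return filtered series, same shape.
#' @export
bandpass <- function(series, low = 0.01, high = 0.1, tr_seconds, order = 4) {
  nyq <- 1 / (2 * tr_seconds)
  if (high >= nyq) {
    stop(sprintf("bandpass: high edge %.3f Hz is at/above Nyquist %.3f Hz",
                 high, nyq))
  }
  if (low <= 0 || low >= high) stop("bandpass: need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  f1 <- function(x) {
    x <- x - mean(x)
    as.numeric(signal::filtfilt(bf, x))
  }
  if (is.matrix(series)) t(apply(series, 1, f1)) else f1(series)
}

#' Polynomial detrending
#'
#' Removes the least-squares polynomial fit of the given order; the
#' residual is orthogonal to all polynomials up to that order.
#'
#' @param series numeric vector or voxels x time matrix (rowwise).
#' @param order polynomial order (default 2: linear + quadratic).
#' @return detrended series.
#' @export
detrend_poly <- function(series, order = 2) {
  n <- if (is.matrix(series)) ncol(series) else length(series)
  if (n <= order + 1) stop("detrend_poly: series length must exceed order + 1")
  x <- stats::poly(seq_len(n), degree = max(order, 1))
  basis <- if (order == 0) cbind(rep(1, n)) else cbind(1, x[, seq_len(order), drop = FALSE])
  q <- qr.Q(qr(basis))
  resid1 <- function(y) as.numeric(y - q %*% crossprod(q, y))
  if (is.matrix(series)) {
    series - tcrossprod(series %*% q, q) -> r
    r
  } else {
    resid1(series)
  }
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary least squares on an intercept plus the supplied regressors;
#' returns residuals, which are orthogonal to every regressor column.
#' The global mean signal is deliberately not among the default regressors.
#'
#' @param series numeric vector or voxels x time matrix (rowwise).
#' @param regressors numeric time x k matrix.
#' @return residual series.
#' @export
nuisance_regress <- function(series, regressors) {
  regressors <- as.matrix(regressors)
  n <- if (is.matrix(series)) ncol(series) else length(series)
  stopifnot(nrow(regressors) == n)
  x <- cbind(intercept = 1, regressors)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), qrx$pivot[seq_len(qrx$rank)])]
    stop("nuisance_regress: rank-deficient regressor matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  q <- qr.Q(qrx)
  if (is.matrix(series)) {
    series - tcrossprod(series %*% q, q)
  } else {
    as.numeric(series - q %*% crossprod(q, series))
  }
}

#' Temporal derivatives of motion regressors
#'
#' First differences with a zero-padded first sample.
#'
#' @param motion time x k matrix.
#' @return time x k matrix of derivatives.
#' @export
motion_derivatives <- function(motion) {
  motion <- as.matrix(motion)
  rbind(0, diff(motion))
}

#' Remove initial samples from a series
#'
#' Drops the first `floor(seconds / tr_seconds)` samples (e.g. 21.6 s at
#' TR 1.8 s removes exactly 12 samples); fractional counts are floored and
#' noted.
#'
#' @param series numeric vector or voxels x time matrix (columns are time).
#' @param seconds duration to remove (default 21.6).
#' @param tr_seconds sampling interval.
#' @return shortened series.
#' @export
drop_initial <- function(series, seconds = 21.6, tr_seconds) {
  k <- floor(seconds / tr_seconds + 1e-9)
  if (abs(k - seconds / tr_seconds) > 1e-9) {
    pv_log(sprintf("drop_initial: %.3f s is not a whole number of samples; flooring to %d",
                   seconds / tr_seconds, k))
  }
  n <- if (is.matrix(series)) ncol(series) else length(series)
  if (k >= n) stop("drop_initial: removal would consume the whole series")
  if (k == 0) return(series)
  if (is.matrix(series)) series[, -seq_len(k), drop = FALSE] else series[-seq_len(k)]
}

#' Spatial Gaussian smoothing within a voxel mask
#'
#' Per-timepoint convolution with an isotropic Gaussian kernel of the given
#' FWHM, restricted to the masked voxels and mask-normalized (kernel
#' weights renormalized over in-mask voxels), so a spatially constant field
#' is preserved exactly. Voxels must lie on a regular lattice.
#'
#' @param dataset a [subject_dataset()].
#' @param fwhm_mm kernel full width at half maximum in mm (default 4).
#' @param truncate_sd kernel support radius in SD units (default 3).
#' @return a `subject_dataset` with smoothed `voxel_series`.
#' @export
smooth_gaussian <- function(dataset, fwhm_mm = 4, truncate_sd = 3) {
  if (fwhm_mm <= 0) return(dataset)
  coords <- dataset$voxel_coords_mm
  .check_regular_lattice(coords)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- dataset$voxel_series
  for (h in unique(dataset$hemisphere)) {
    sel <- dataset$hemisphere == h
    d2 <- as.matrix(stats::dist(coords[sel, , drop = FALSE]))^2
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > (truncate_sd * sigma)^2] <- 0
    w <- w / rowSums(w)
    out[sel, ] <- w %*% dataset$voxel_series[sel, , drop = FALSE]
  }
  dataset$voxel_series <- out
  dataset
}

.check_regular_lattice <- function(coords, tol = 1e-6) {
  for (j in 1:3) {
    u <- sort(unique(round(coords[, j], 8)))
    if (length(u) > 1) {
      steps <- diff(u)
      if (max(abs(steps / min(steps) - round(steps / min(steps)))) > tol) {
        stop("smooth_gaussian: voxel coordinates are not on a regular lattice (axis ",
             j, ")")
      }
    }
  }
  invisible(TRUE)
}

#' Full correlation-analysis preprocessing for one subject
#'
#' Applies, in order: initial-sample removal, despiking, band-pass
#' filtering, polynomial detrending, nuisance regression (motion
#' parameters + their temporal derivatives, ventricle and white-matter
#' signals when present in `dataset$nuisance`; never the global mean), and
#' finally within-mask spatial smoothing of the thalamic voxel data.
#' The same temporal steps are applied to `area_series` when given.
#'
#' @param dataset a [subject_dataset()].
#' @param area_series optional areas x time matrix for the same subject.
#' @param drop_seconds initial duration to discard (default 21.6).
#' @param despike_sd despike threshold (default 2.5).
#' @param band band edges in Hz (default `c(0.01, 0.1)`).
#' @param detrend_order polynomial order (default 2).
#' @param fwhm_mm spatial smoothing FWHM in mm (default 4; 0 disables).
#' @return list with `dataset` (preprocessed) and `area_series`.
#' @export
preprocess_subject <- function(dataset, area_series = NULL,
                               drop_seconds = 21.6, despike_sd = 2.5,
                               band = c(0.01, 0.1), detrend_order = 2,
                               fwhm_mm = 4) {
  tr <- dataset$tr_seconds
  steps <- function(x) {
    x <- drop_initial(x, drop_seconds, tr)
    x <- despike(x, despike_sd)
    x <- bandpass(x, band[1], band[2], tr)
    x <- detrend_poly(x, detrend_order)
    x
  }
  nt_new <- ncol(steps(dataset$voxel_series[1, , drop = FALSE]))
  regs <- NULL
  if (!is.null(dataset$nuisance)) {
    mot <- as.matrix(dataset$nuisance$motion)
    regs <- cbind(mot, motion_derivatives(mot),
                  ventricle = dataset$nuisance$ventricle,
                  white_matter = dataset$nuisance$white_matter)
    regs <- drop_initial(t(regs), drop_seconds, tr)
    regs <- t(regs)
  }
  vox <- steps(dataset$voxel_series)
  if (!is.null(regs)) vox <- nuisance_regress(vox, regs)
  dataset$voxel_series <- vox
  dataset$nuisance <- NULL
  if (fwhm_mm > 0) dataset <- smooth_gaussian(dataset, fwhm_mm)
  pv_log(sprintf("preprocess_subject %s: %d -> %d timepoints",
                 dataset$subject_id, nt_new + floor(drop_seconds / tr), nt_new))
  out_area <- NULL
  if (!is.null(area_series)) {
    out_area <- steps(as.matrix(area_series))
    if (!is.null(regs)) out_area <- nuisance_regress(out_area, regs)
    rownames(out_area) <- rownames(area_series)
  }
  list(dataset = dataset, area_series = out_area)
}

#' Preprocess every subject of a resting dataset
#'
#' @param rest a `rest_dataset` from [generate_resting_dataset()] (or a
#'   compatible list).
#' @param ... passed to [preprocess_subject()].
#' @return the dataset with conditioned voxel and area series.
#' @export
preprocess_dataset <- function(rest, ...) {
  for (s in seq_along(rest$subjects)) {
    pp <- preprocess_subject(rest$subjects[[s]], rest$areas$series[[s]], ...)
    rest$subjects[[s]] <- pp$dataset
    rest$areas$series[[s]] <- pp$area_series
  }
  rest
}
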