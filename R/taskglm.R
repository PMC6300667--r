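# Block-design GLM, d-prime tuning indices, leave-one-out category ROI
# analysis, and group statistics.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities peaking at ~6 s with an undershoot at
#' ~16 s, normalized to unit peak.
#'
#' @param t time in seconds (nonnegative).
#' @param peak1,peak2 response / undershoot peak times.
#' @param ratio undershoot amplitude ratio (default 1/6).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak1 = 6, peak2 = 16, ratio = 1 / 6) {
  # gamma density with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = peak1 + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = peak2 + 1, rate = 1)
  h / max(h)
}

#' Build a block-design matrix
#'
#' Condition regressors are 0/1 square waves matching the block timing,
#' convolved with the requested HRF on a fine time grid and sampled at TR
#' instants; baseline (intercept), linear drift and any supplied nuisance
#' columns are appended.
#'
#' @param block_table data frame with `onset`, `duration` (s), `condition`.
#' @param hrf_spec `"double-gamma"` or `"delta"` (identity kernel).
#' @param tr repetition time (s).
#' @param n_timepoints run length in samples.
#' @param nuisance optional time x k matrix of extra regressors.
#' @param dt_seconds fine grid step for convolution (default 0.1).
#' @return object of class `design_matrix`: list with `matrix` (time x p),
#'   `condition_columns`, `tr_seconds`, `n_timepoints`.
#' @export
build_design <- function(block_table, hrf_spec = "double-gamma", tr,
                         n_timepoints, nuisance = NULL, dt_seconds = 0.1) {
  run_len <- n_timepoints * tr
  if (nrow(block_table) > 0 &&
      any(block_table$onset + block_table$duration > run_len + 1e-9)) {
    stop("build_design: block extends past end of run")
  }
  conds <- if (nrow(block_table)) sort(unique(as.character(block_table$condition))) else character(0)
  nf <- round(run_len / dt_seconds)
  tfine <- (seq_len(nf) - 1) * dt_seconds
  hrf <- switch(hrf_spec,
    "double-gamma" = hrf_double_gamma(seq(0, 32, by = dt_seconds)),
    "delta" = 1,
    stop("build_design: unknown hrf_spec '", hrf_spec, "'"))
  cols <- lapply(conds, function(cc) {
    b <- block_table[block_table$condition == cc, , drop = FALSE]
    sq <- numeric(nf)
    for (i in seq_len(nrow(b))) {
      sq[tfine >= b$onset[i] - 1e-9 & tfine < b$onset[i] + b$duration[i] - 1e-9] <- 1
    }
    conv <- stats::convolve(sq, rev(hrf), type = "open")[seq_len(nf)]
    if (length(hrf) > 1) conv <- conv * dt_seconds  # Riemann sum scaling
    idx <- pmin(nf, round(((seq_len(n_timepoints) - 1) * tr) / dt_seconds) + 1)
    conv[idx]
  })
  x <- do.call(cbind, c(cols, list(baseline = rep(1, n_timepoints),
                                   drift = seq_len(n_timepoints) - (n_timepoints + 1) / 2)))
  colnames(x) <- c(conds, "baseline", "drift")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    colnames(nuisance) <- colnames(nuisance) %||% paste0("nuis", seq_len(ncol(nuisance)))
    x <- cbind(x, nuisance)
  }
  if (qr(x)$rank < ncol(x)) stop("build_design: design matrix is rank deficient")
  structure(list(matrix = x, condition_columns = conds, tr_seconds = tr,
                 n_timepoints = n_timepoints),
            class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a voxelwise GLM
#'
#' Ordinary least squares of every voxel's series on the design matrix,
#' with t statistics for the requested contrasts of condition betas.
#'
#' @param dataset a [subject_dataset()] or voxels x time matrix.
#' @param design a [build_design()] result.
#' @param contrasts named list of numeric contrast vectors over the
#'   condition columns (e.g. `list(face_vs_scene = c(1, -1))`).
#' @return object of class `glm_fit`: `betas` (voxels x p), `sigma2`,
#'   `df`, and per-contrast `value`, `t`, `p` matrices (voxels x contrasts).
#' @export
fit_glm <- function(dataset, design, contrasts = list()) {
  y <- if (inherits(dataset, "subject_dataset")) dataset$voxel_series else as.matrix(dataset)
  x <- design$matrix
  if (ncol(y) != nrow(x)) stop("fit_glm: timepoints of data and design differ")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) stop("fit_glm: rank-deficient design")
  betas <- t(qr.coef(qrx, t(y)))
  fitted <- betas %*% t(x)
  res <- y - fitted
  df <- ncol(y) - ncol(x)
  sigma2 <- rowSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  ncond <- length(design$condition_columns)
  con <- lapply(contrasts, function(cv) {
    cfull <- numeric(ncol(x))
    cfull[seq_len(ncond)] <- cv
    val <- as.numeric(betas %*% cfull)
    se <- sqrt(sigma2 * as.numeric(t(cfull) %*% xtx_inv %*% cfull))
    tstat <- val / se
    list(value = val, t = tstat, p = 2 * stats::pt(-abs(tstat), df))
  })
  structure(list(betas = betas, sigma2 = sigma2, df = df, contrasts = con,
                 design = design, residuals = res),
            class = "glm_fit")
}

#' d-prime tuning index
#'
#' Standardized response difference
#' `(mu_a - mu_b) / sqrt((sd_a^2 + sd_b^2) / 2)`, used as the laterality
#' index (contralateral vs ipsilateral stimulation) and the attentional
#' modulation index (attended vs unattended contralateral stimulation).
#'
#' @param mu_a,mu_b mean responses of the two conditions.
#' @param sd_a,sd_b response SDs across blocks.
#' @return numeric d-prime (vectorized).
#' @export
dprime_index <- function(mu_a, sd_a, mu_b, sd_b) {
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (any(pooled == 0)) stop("dprime_index: both SDs are zero; index undefined")
  (mu_a - mu_b) / pooled
}

#' Per-block response means and SDs for a condition
#'
#' For each block of a condition, averages the series over a window equal
#' to the block duration, lagged from block onset by the HRF peak latency
#' (hemodynamic delay); returns the mean and SD over blocks. This is the
#' estimator behind the d-prime indices.
#'
#' @param series numeric vector or voxels x time matrix.
#' @param block_table data frame with `onset`, `duration`, `condition`.
#' @param condition condition to summarize.
#' @param tr_seconds sampling interval.
#' @param lag_seconds hemodynamic lag (default 6, the HRF peak).
#' @return list with `mu` and `sd` (scalars or per-voxel vectors).
#' @export
block_response_stats <- function(series, block_table, condition, tr_seconds,
                                 lag_seconds = 6) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  b <- block_table[block_table$condition == condition, , drop = FALSE]
  if (nrow(b) == 0) stop("block_response_stats: no blocks for condition ", condition)
  vals <- sapply(seq_len(nrow(b)), function(i) {
    from <- floor((b$onset[i] + lag_seconds) / tr_seconds) + 1
    to <- min(ncol(series),
              ceiling((b$onset[i] + lag_seconds + b$duration[i]) / tr_seconds))
    rowMeans(series[, from:to, drop = FALSE])
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(series))
  list(mu = rowMeans(vals), sd = apply(vals, 1, stats::sd))
}

#' Laterality and attention d-prime indices for a block dataset
#'
#' Computes per-voxel laterality (contralateral vs ipsilateral stimulation
#' under central fixation) and attentional-modulation (attended vs
#' unattended contralateral stimulation) d-prime indices per subject.
#'
#' @param block_ds a `block_dataset` from [generate_laterality_dataset()].
#' @param lag_seconds hemodynamic lag for the block window.
#' @return list with matrices `laterality` and `attention` (voxels x subjects).
#' @export
tuning_indices <- function(block_ds, lag_seconds = 6) {
  bt <- block_ds$block_table
  lat <- att <- NULL
  for (s in seq_along(block_ds$subjects)) {
    y <- block_ds$subjects[[s]]$voxel_series
    tr <- block_ds$subjects[[s]]$tr_seconds
    contra <- block_response_stats(y, bt, "stim_contra", tr, lag_seconds)
    ipsi <- block_response_stats(y, bt, "stim_ipsi", tr, lag_seconds)
    attc <- block_response_stats(y, bt, "att_contra", tr, lag_seconds)
    lat <- cbind(lat, dprime_index(contra$mu, contra$sd, ipsi$mu, ipsi$sd))
    att <- cbind(att, dprime_index(attc$mu, attc$sd, contra$mu, contra$sd))
  }
  list(laterality = lat, attention = att)
}

#' Precision-weighted group z map
#'
#' Inverse-variance-weighted one-sample z across subjects (a closed-form
#' mixed-effects-style group test): z = sum(b/v) / sqrt(sum(1/v)).
#'
#' @param betas voxels x subjects matrix of effect estimates.
#' @param variances voxels x subjects matrix of their sampling variances.
#' @return list with per-voxel `z` and two-tailed `p`.
#' @export
precision_weighted_group <- function(betas, variances) {
  w <- 1 / variances
  z <- rowSums(betas * w) / sqrt(rowSums(w))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# connected components on a lattice (6-neighborhood), for ROI cluster rules
.connected_components <- function(coords, sel, spacing) {
  idx <- which(sel)
  if (!length(idx)) return(integer(0))
  comp <- rep(NA_integer_, length(idx))
  key <- function(p) paste(round(p / spacing), collapse = ",")
  lookup <- stats::setNames(seq_along(idx), apply(coords[idx, , drop = FALSE], 1, key))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)) * spacing
  cid <- 0L
  for (i in seq_along(idx)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      p <- coords[idx[j], ]
      for (k in 1:6) {
        nb <- lookup[key(p + offs[k, ])]
        if (!is.na(nb) && is.na(comp[nb])) {
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
    }
  }
  out <- rep(NA_integer_, length(sel))
  out[idx] <- comp
  out
}

#' Leave-one-out category ROI analysis
#'
#' For each subject, an n-1 pseudo-group contrast map (precision-weighted z
#' across the other subjects) defines a category-selective ROI —
#' thresholded at FDR q, restricted to the posterior-medial(-ventral)
#' octant of the mask, largest connected cluster — and the held-out
#' subject's mean betas per condition are extracted from it. No subject's
#' own data enters its ROI definition.
#'
#' @param contrast_values voxels x subjects matrix (e.g. face minus scene).
#' @param contrast_vars voxels x subjects sampling variances of the values.
#' @param betas_by_condition named list of voxels x subjects beta matrices.
#' @param coords voxels x 3 mm coordinates (shared grid).
#' @param q FDR threshold (default 0.05).
#' @param restrict logical per-voxel mask (default: posterior-medial-ventral
#'   octant computed from `coords`, assuming right-hemisphere coordinates).
#' @param spacing_mm lattice spacing for connectivity (default inferred).
#' @return data frame: one row per subject x condition with `mean_beta`,
#'   plus the ROI size per fold.
#' @export
loo_category_roi <- function(contrast_values, contrast_vars,
                             betas_by_condition, coords, q = 0.05,
                             restrict = NULL, spacing_mm = NULL) {
  n_sub <- ncol(contrast_values)
  if (n_sub < 3) stop("loo_category_roi: need at least 3 subjects")
  coords <- as.matrix(coords)
  if (is.null(restrict)) {
    restrict <- coords[, 2] <= stats::median(coords[, 2]) &
      abs(coords[, 1]) <= stats::median(abs(coords[, 1])) &
      coords[, 3] <= stats::median(coords[, 3])
  }
  if (is.null(spacing_mm)) {
    ux <- sort(unique(coords[, 1]))
    spacing_mm <- if (length(ux) > 1) min(diff(ux)) else 1
  }
  rows <- list()
  for (s in seq_len(n_sub)) {
    keep <- setdiff(seq_len(n_sub), s)
    g <- precision_weighted_group(contrast_values[, keep, drop = FALSE],
                                  contrast_vars[, keep, drop = FALSE])
    qv <- stats::p.adjust(g$p, method = "BH")
    sel <- qv < q & g$z > 0 & restrict
    if (!any(sel)) {
      stop(sprintf("loo_category_roi: empty ROI for fold %d at FDR q = %g", s, q))
    }
    comp <- .connected_components(coords, sel, spacing_mm)
    sizes <- table(comp[!is.na(comp)])
    best <- as.integer(names(sizes)[which.max(sizes)])
    roi <- !is.na(comp) & comp == best
    for (cond in names(betas_by_condition)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, condition = cond,
        mean_beta = mean(betas_by_condition[[cond]][roi, s]),
        roi_size = sum(roi))
    }
  }
  do.call(rbind, rows)
}

#' Group statistics with multiple-comparison correction
#'
#' One-sample tests across subjects per entry (voxel/area/ROI), two-tailed,
#' with Benjamini-Hochberg FDR adjustment and Cohen's d. Correlation-valued
#' inputs should be Fisher-z transformed first (set `fisher = TRUE`).
#'
#' @param values entries x subjects matrix (or vector for one entry).
#' @param test `"one_sample_t"` or `"wilcoxon"` (signed rank).
#' @param mu null value (default 0).
#' @param fisher transform values by atanh before testing.
#' @param q FDR level for the `significant` flag (default 0.05).
#' @return data frame with `estimate`, `statistic`, `p`, `q` (BH-adjusted),
#'   `cohen_d`, `significant`.
#' @export
group_stats <- function(values, test = c("one_sample_t", "wilcoxon"),
                        mu = 0, fisher = FALSE, q = 0.05) {
  test <- match.arg(test)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) < 2) stop("group_stats: need at least 2 subjects")
  if (fisher) values <- fisher_z(values)
  n <- ncol(values)
  est <- rowMeans(values)
  sds <- apply(values, 1, stats::sd)
  flagged <- sds == 0
  if (any(flagged)) pv_log("group_stats: constant entries across subjects; p undefined")
  stat <- p <- rep(NA_real_, nrow(values))
  if (test == "one_sample_t") {
    stat[!flagged] <- (est[!flagged] - mu) / (sds[!flagged] / sqrt(n))
    p[!flagged] <- 2 * stats::pt(-abs(stat[!flagged]), n - 1)
  } else {
    for (i in which(!flagged)) {
      wt <- stats::wilcox.test(values[i, ], mu = mu, exact = TRUE)
      stat[i] <- unname(wt$statistic)
      p[i] <- wt$p.value
    }
  }
  qv <- rep(NA_real_, length(p))
  qv[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(estimate = est, statistic = stat, p = p, q = qv,
             cohen_d = ifelse(sds > 0, (est - mu) / sds, NA_real_),
             significant = !is.na(qv) & qv < q)
}
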