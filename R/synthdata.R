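# Multi-subject synthetic fMRI generator.
#
# The generators emulate the statistical structure the coupling analyses
# assume: cortical area signals organized into two planted networks
# (occipito-temporal and fronto-parietal), thalamic voxels as noisy,
# spatially topographic mixtures of area signals, movie responses with
# short vs long temporal receptive windows, block-design runs with planted
# effect sizes, and nuisance structure (polynomial drifts, spikes,
# motion-correlated noise, ventricle/white-matter-like global components).
# Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults define the reference study conditions: 13 subjects, the 39-area
#' bilateral area set, a 5 x 5 x 6 voxel lattice per hemisphere (2 mm
#' spacing) split into a ventral and a dorsal compartment, 10-minute rest
#' runs at TR 1.8 s, and a latent covariance in which areas of the same
#' network correlate up to `within_network_corr` and areas of different
#' networks correlate at `between_network_corr`. The within-network excess
#' is carried partly by a shared network factor (fraction `network_floor`,
#' uniform across the network so the planted networks stay assortative)
#' and partly by a Gaussian kernel over the functional hierarchy (length
#' `gradient_length`), which grades profiles along the planted gradient.
#'
#' @param n_subjects number of simulated subjects.
#' @param areas an [area_set()]; defaults to [default_area_set()].
#' @param voxel_dims integer length-3 lattice dimensions per hemisphere.
#' @param voxel_spacing_mm lattice spacing in mm.
#' @param tr_seconds repetition time (s).
#' @param n_timepoints samples per run.
#' @param noise_sd white-noise SD added to each thalamic voxel.
#' @param area_noise_sd measurement-noise SD added to each area series.
#' @param within_network_corr peak correlation between same-network areas.
#' @param between_network_corr correlation between areas of different networks.
#' @param network_floor fraction of the within-network correlation excess
#'   carried by the uniform network factor (the rest decays along the
#'   gradient kernel); in `[0, 1]`.
#' @param gradient_length Gaussian-kernel length (gradient units in `[0,1]`)
#'   over which the graded part of within-network correlation decays toward
#'   the network floor.
#' @param topography_width width (gradient units) of each voxel's Gaussian
#'   weighting over its compartment's areas.
#' @param nuisance_scale overall amplitude of injected nuisance structure
#'   (set 0 to disable drifts/spikes/motion components).
#' @param seed master integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 13,
                       areas = default_area_set(),
                       voxel_dims = c(5, 5, 6),
                       voxel_spacing_mm = 2,
                       tr_seconds = 1.8,
                       n_timepoints = 312,
                       noise_sd = 1.0,
                       area_noise_sd = 0.3,
                       within_network_corr = 0.4,
                       between_network_corr = 0.1,
                       network_floor = 0.5,
                       gradient_length = 0.25,
                       topography_width = 0.15,
                       nuisance_scale = 1.0,
                       seed = 1L) {
  cfg <- structure(
    list(n_subjects = n_subjects, areas = areas, voxel_dims = voxel_dims,
         voxel_spacing_mm = voxel_spacing_mm, tr_seconds = tr_seconds,
         n_timepoints = n_timepoints, noise_sd = noise_sd,
         area_noise_sd = area_noise_sd,
         within_network_corr = within_network_corr,
         between_network_corr = between_network_corr,
         network_floor = network_floor,
         gradient_length = gradient_length,
         topography_width = topography_width,
         nuisance_scale = nuisance_scale, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d subjects, %d areas x %d hemi, %d voxels/hemi, %d tp @ TR %.2fs, seed %d\n",
    x$n_subjects, length(unique(x$areas$name)), length(x$areas$hemispheres),
    prod(x$voxel_dims), x$n_timepoints, x$tr_seconds, x$seed))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  if (cfg$within_network_corr <= cfg$between_network_corr) {
    stop(sprintf(
      "invalid sim_config: within_network_corr (%.3f) must exceed between_network_corr (%.3f)",
      cfg$within_network_corr, cfg$between_network_corr))
  }
  if (cfg$between_network_corr < 0 || cfg$within_network_corr > 1) {
    stop("invalid sim_config: correlations must satisfy 0 <= between < within <= 1")
  }
  if (is.null(cfg$network_floor) || cfg$network_floor < 0 || cfg$network_floor > 1) {
    stop("invalid sim_config: network_floor must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$area_noise_sd < 0) stop("invalid sim_config: negative noise SD")
  if (cfg$tr_seconds <= 0 || cfg$n_timepoints < 3) stop("invalid sim_config: bad time axis")
  sig <- latent_covariance(cfg)
  ev <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop(sprintf(
      "latent covariance not positive semi-definite (min eigenvalue %.3g) for within=%.3f between=%.3f gradient_length=%.3f",
      ev, cfg$within_network_corr, cfg$between_network_corr, cfg$gradient_length))
  }
  invisible(cfg)
}

#' Latent area covariance implied by a simulation config
#'
#' Unit-diagonal covariance over one hemisphere's areas: a rank-one global
#' component at `between_network_corr`, plus within each network a uniform
#' network-factor component (fraction `network_floor` of the within-network
#' excess) and a Gaussian kernel over the planted hierarchy coordinate that
#' raises functionally adjacent areas to `within_network_corr`, plus an
#' idiosyncratic diagonal remainder. Each component is PSD, so the sum is.
#'
#' @param cfg a `sim_config`.
#' @return covariance matrix (areas of one hemisphere).
#' @export
latent_covariance <- function(cfg) {
  idx <- area_hemi_idx(cfg$areas, cfg$areas$hemispheres[1])
  net <- cfg$areas$network[idx]
  g <- cfg$areas$gradient[idx]
  n <- length(idx)
  same <- outer(net, net, "==")
  kern <- exp(-outer(g, g, "-")^2 / (2 * cfg$gradient_length^2))
  excess <- cfg$within_network_corr - cfg$between_network_corr
  f <- cfg$network_floor
  sig <- matrix(cfg$between_network_corr, n, n) +
    excess * (f + (1 - f) * kern) * same
  diag(sig) <- 1
  dimnames(sig) <- list(cfg$areas$name[idx], cfg$areas$name[idx])
  sig
}

# Voxel lattice for one hemisphere, centered on a pulvinar-like location.
# Right hemisphere center (14, -28, 4) mm; left mirrored across x = 0.
.voxel_lattice <- function(cfg, hemi) {
  d <- cfg$voxel_dims
  sp <- cfg$voxel_spacing_mm
  center <- c(14, -28, 4)
  if (hemi == "L") center[1] <- -center[1]
  gx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp
  gy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp
  gz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp
  coords <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sweep(coords, 2, center, "+")
}

# Planted topography for one hemisphere: voxels in the lower half of the
# lattice form the ventral compartment (mixing occipito-temporal areas),
# upper half the dorsal compartment (fronto-parietal areas). Within each
# compartment the preferred hierarchy position runs along an
# anterior-lateral -> posterior-medial axis (ventral) or a
# posterior -> anterior axis (dorsal).
.voxel_topography <- function(cfg, hemi) {
  coords <- .voxel_lattice(cfg, hemi)
  zmid <- stats::median(coords[, 3])
  compartment <- ifelse(coords[, 3] < zmid, "ventral", "dorsal")
  lateral_sign <- if (hemi == "R") 1 else -1
  axis_v <- c(-lateral_sign, -1, 0) / sqrt(2)   # toward posterior-medial
  axis_d <- c(0, 1, 0)                          # toward anterior
  u <- numeric(nrow(coords))
  for (comp in c("ventral", "dorsal")) {
    sel <- compartment == comp
    ax <- if (comp == "ventral") axis_v else axis_d
    proj <- coords[sel, , drop = FALSE] %*% ax
    u[sel] <- (proj - min(proj)) / (max(proj) - min(proj))
  }
  idx <- area_hemi_idx(cfg$areas, hemi)
  net <- cfg$areas$network[idx]
  g <- cfg$areas$gradient[idx]
  vnet <- ifelse(compartment == "ventral", "occipito-temporal", "fronto-parietal")
  w <- exp(-outer(u, g, "-")^2 / (2 * cfg$topography_width^2)) *
    outer(vnet, net, "==")
  w <- w / sqrt(pmax(rowSums(w^2), .Machine$double.eps))
  list(coords = coords, compartment = compartment, gradient = u, weights = w)
}

# Smooth per-subject nuisance structure: quadratic drift, six random-walk
# motion series, ventricle- and white-matter-like global components, and
# sparse spikes. Returns the additive voxel/area contamination plus the
# "measured" regressor series.
.make_nuisance <- function(cfg, n_vox, n_areas) {
  tt <- seq_len(cfg$n_timepoints) / cfg$n_timepoints
  s <- cfg$nuisance_scale
  motion <- sapply(seq_len(6), function(i) cumsum(stats::rnorm(cfg$n_timepoints, 0, 0.05)))
  motion <- scale(motion, center = TRUE, scale = FALSE)
  vent <- as.numeric(stats::filter(stats::rnorm(cfg$n_timepoints), rep(1 / 5, 5),
                                   circular = TRUE))
  wm <- as.numeric(stats::filter(stats::rnorm(cfg$n_timepoints), rep(1 / 5, 5),
                                 circular = TRUE))
  drift_vox <- outer(stats::rnorm(n_vox, 0, 0.5), tt) +
    outer(stats::rnorm(n_vox, 0, 0.5), tt^2)
  drift_area <- outer(stats::rnorm(n_areas, 0, 0.5), tt) +
    outer(stats::rnorm(n_areas, 0, 0.5), tt^2)
  mload_vox <- matrix(stats::rnorm(n_vox * 6, 0, 0.15), n_vox, 6)
  mload_area <- matrix(stats::rnorm(n_areas * 6, 0, 0.15), n_areas, 6)
  gload_vox <- matrix(stats::rnorm(n_vox * 2, 0, 0.2), n_vox, 2)
  gload_area <- matrix(stats::rnorm(n_areas * 2, 0, 0.2), n_areas, 2)
  glob <- rbind(vent, wm)
  spikes <- matrix(0, n_vox, cfg$n_timepoints)
  n_spk <- max(1, round(0.002 * n_vox * cfg$n_timepoints))
  spk_idx <- cbind(sample.int(n_vox, n_spk, replace = TRUE),
                   sample.int(cfg$n_timepoints, n_spk, replace = TRUE))
  spikes[spk_idx] <- stats::rnorm(n_spk, 0, 6)
  list(
    voxel_add = s * (drift_vox + mload_vox %*% t(motion) + gload_vox %*% glob + spikes),
    area_add = s * (drift_area + mload_area %*% t(motion) + gload_area %*% glob),
    regressors = list(motion = motion, ventricle = vent, white_matter = wm)
  )
}

#' Generate a multi-subject synthetic resting-state dataset
#'
#' Draws, per subject and hemisphere, latent area series from the
#' configured network covariance; observed area series add measurement
#' noise and nuisance structure; each thalamic voxel is a topography-
#' weighted mixture of its compartment's area latents plus white noise and
#' nuisance structure. Deterministic given `config` (which carries the seed).
#'
#' @param config a [sim_config()].
#' @return list of class `rest_dataset` with elements `subjects` (list of
#'   [subject_dataset()]), `areas` (the `area_set`, with `$series`: one
#'   areas x time matrix per subject), `truth` ([sim_truth()]) and `config`.
#' @export
generate_resting_dataset <- function(config) {
  validate_sim_config(config)
  cfg <- config
  hemis <- cfg$areas$hemispheres
  sig <- latent_covariance(cfg)
  cl <- chol(sig + diag(1e-10, nrow(sig)))
  topo <- lapply(hemis, function(h) .voxel_topography(cfg, h))
  names(topo) <- hemis
  n_area_h <- nrow(sig)
  n_vox_h <- prod(cfg$voxel_dims)
  n_areas_tot <- length(cfg$areas$name)
  n_vox_tot <- n_vox_h * length(hemis)

  out <- with_seed(substream_seed(cfg$seed, "rest"), {
    subjects <- vector("list", cfg$n_subjects)
    area_series <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      nuis <- .make_nuisance(cfg, n_vox_tot, n_areas_tot)
      vox_all <- NULL; area_all <- NULL; coords_all <- NULL; hemi_all <- NULL
      for (h in hemis) {
        z <- matrix(stats::rnorm(n_area_h * cfg$n_timepoints),
                    n_area_h, cfg$n_timepoints)
        lat <- t(cl) %*% z
        obs <- lat + cfg$area_noise_sd *
          matrix(stats::rnorm(length(lat)), nrow(lat), ncol(lat))
        vox <- topo[[h]]$weights %*% lat + cfg$noise_sd *
          matrix(stats::rnorm(n_vox_h * cfg$n_timepoints), n_vox_h)
        vox_all <- rbind(vox_all, vox)
        area_all <- rbind(area_all, obs)
        coords_all <- rbind(coords_all, topo[[h]]$coords)
        hemi_all <- c(hemi_all, rep(h, n_vox_h))
      }
      vox_all <- vox_all + nuis$voxel_add
      area_all <- area_all + nuis$area_add
      rownames(area_all) <- paste(cfg$areas$name, cfg$areas$hemisphere, sep = "_")
      subjects[[s]] <- subject_dataset(
        vox_all, cfg$tr_seconds, coords_all, hemi_all,
        subject_id = sprintf("S%02d", s), nuisance = nuis$regressors)
      area_series[[s]] <- area_all
    }
    list(subjects = subjects, area_series = area_series)
  })

  voxel_gradient <- do.call(rbind, lapply(hemis, function(h) {
    data.frame(hemisphere = h, compartment = topo[[h]]$compartment,
               gradient = topo[[h]]$gradient)
  }))
  peak <- do.call(rbind, lapply(hemis, function(h) {
    idx <- area_hemi_idx(cfg$areas, h)
    pk <- apply(topo[[h]]$weights, 2, which.max)
    data.frame(area = cfg$areas$name[idx], hemisphere = h, voxel = pk,
               x = topo[[h]]$coords[pk, 1], y = topo[[h]]$coords[pk, 2],
               z = topo[[h]]$coords[pk, 3],
               gradient = cfg$areas$gradient[idx])
  }))
  idx1 <- area_hemi_idx(cfg$areas, hemis[1])
  truth <- sim_truth(
    network_assignment = stats::setNames(cfg$areas$network[idx1],
                                         cfg$areas$name[idx1]),
    voxel_gradient = voxel_gradient,
    planted_peak = peak
  )
  areas <- cfg$areas
  areas$series <- out$area_series
  structure(list(subjects = out$subjects, areas = areas, truth = truth,
                 config = cfg),
            class = "rest_dataset")
}

#' @export
print.rest_dataset <- function(x, ...) {
  cat(sprintf("rest_dataset: %d subjects, %d area rows, %d voxels, %d tp\n",
              length(x$subjects), length(x$areas$name),
              nrow(x$subjects[[1]]$voxel_series), ncol(x$subjects[[1]]$voxel_series)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Movie (temporal receptive window) simulation

#' Generate a smooth stimulus feature time course
#'
#' Gaussian-process-like feature course: white noise convolved with a
#' Gaussian kernel (SD `smooth_seconds`), standardized. Sampled on a fine
#' grid (`dt_seconds`) so that sub-second scrambling segments are resolved.
#'
#' @param duration_seconds total duration.
#' @param dt_seconds sampling step of the fine grid.
#' @param smooth_seconds kernel SD controlling temporal autocorrelation.
#' @param seed integer seed.
#' @return object of class `stimulus_course`: list with `values`, `dt`.
#' @export
generate_stimulus_course <- function(duration_seconds, dt_seconds = 0.1,
                                     smooth_seconds = 3, seed = 1L) {
  n <- round(duration_seconds / dt_seconds)
  with_seed(substream_seed(seed, "stimulus"), {
    k <- stats::dnorm(seq(-4, 4, length.out = round(8 * smooth_seconds / dt_seconds)))
    k <- k / sum(k)
    pad <- length(k)
    w <- stats::rnorm(n + 2 * pad)
    sm <- stats::filter(w, k, sides = 2)
    v <- as.numeric(sm[(pad + 1):(pad + n)])
    v <- (v - mean(v)) / stats::sd(v)
    structure(list(values = v, dt = dt_seconds), class = "stimulus_course")
  })
}

#' Scramble a stimulus course into reordered short segments
#'
#' Cuts the course into contiguous segments with lengths drawn uniformly
#' from `[segment_min, segment_max]` seconds (the final remainder segment is
#' kept and permuted with the rest) and reorders them by a random
#' permutation. The sample multiset is exactly preserved.
#'
#' @param stimulus a `stimulus_course` (or numeric vector with `dt` attr).
#' @param segment_min,segment_max segment-length bounds in seconds.
#' @param seed integer seed.
#' @return list of class `scrambled_stimulus`: `values`, `dt`, `segments`
#'   (data frame of original start/end sample per segment) and
#'   `permutation` (new order of segments).
#' @export
scramble_stimulus <- function(stimulus, segment_min = 0.5, segment_max = 1.6,
                              seed = 1L) {
  if (segment_min <= 0 || segment_max <= 0 || segment_max < segment_min) {
    stop("scramble_stimulus: segment bounds must be positive with max >= min")
  }
  v <- stimulus$values
  dt <- stimulus$dt
  n <- length(v)
  if (n * dt < segment_max) stop("scramble_stimulus: stimulus shorter than segment_max")
  with_seed(substream_seed(seed, "scramble"), {
    starts <- integer(0); ends <- integer(0); pos <- 1L
    while (pos <= n) {
      len <- max(1L, round(stats::runif(1, segment_min, segment_max) / dt))
      end <- min(n, pos + len - 1L)
      starts <- c(starts, pos); ends <- c(ends, end)
      pos <- end + 1L
    }
    perm <- sample.int(length(starts))
    out <- unlist(lapply(perm, function(i) v[starts[i]:ends[i]]))
    structure(
      list(values = out, dt = dt,
           segments = data.frame(start = starts, end = ends),
           permutation = perm),
      class = c("scrambled_stimulus", "stimulus_course"))
  })
}

#' Region response to a stimulus course under a temporal receptive window
#'
#' Short-window (instantaneous) regions respond pointwise to the stimulus;
#' long-window regions respond with a trailing moving average over
#' `window_seconds` of stimulus history. The noiseless response is shared
#' across subjects and sampled at TR instants.
#'
#' @param stimulus a `stimulus_course`.
#' @param window_seconds 0 (or < dt) for instantaneous, else trailing window.
#' @param tr_seconds repetition time used for sampling.
#' @return numeric response, one value per TR.
#' @export
trw_response <- function(stimulus, window_seconds, tr_seconds) {
  v <- stimulus$values
  dt <- stimulus$dt
  n <- length(v)
  if (window_seconds * 1.0 > n * dt) stop("trw_response: window longer than run")
  if (window_seconds >= dt * 1.5) {
    w <- max(1L, round(window_seconds / dt))
    cs <- cumsum(v)
    resp_fine <- (cs - c(rep(0, w), utils::head(cs, -w))) /
      pmin(seq_len(n), w)
  } else {
    resp_fine <- v
  }
  idx <- round(seq(tr_seconds, n * dt, by = tr_seconds) / dt)
  idx <- idx[idx >= 1 & idx <= n]
  resp_fine[idx]
}

#' Generate a multi-subject movie-viewing dataset with short and long TRW regions
#'
#' One intact stimulus course and one segment-scrambled version (a single
#' shared permutation, as all subjects viewed the same scrambled movie) are
#' generated; each region's noiseless response is a fixed function of the
#' stimulus (pointwise or trailing moving average), shared across subjects;
#' each subject/voxel/repetition adds independent Gaussian noise.
#'
#' @param config a [sim_config()]; `tr_seconds` defaults here to the movie
#'   protocol (1.5 s) if the config still holds the rest default.
#' @param trw_spec named numeric vector, region -> window length in seconds
#'   (0 = instantaneous). Default `c(ventral = 0, dorsal = 12)`.
#' @param n_subjects number of movie subjects (default 11).
#' @param duration_seconds movie clip length (default 345 s, i.e. 5 min 45 s).
#' @param n_voxels_per_region voxels per simulated region.
#' @param n_repetitions repetitions per condition per subject (default 2).
#' @param noise_sd per-repetition voxel noise SD (default 1.6).
#' @return list of class `movie_dataset` with `responses` (nested list
#'   `condition -> subject -> region` of voxel x time matrices), `stimulus`,
#'   `scrambled_stimulus`, `tr_seconds`, and `truth` (TRW labels).
#' @export
generate_movie_dataset <- function(config = sim_config(),
                                   trw_spec = c(ventral = 0, dorsal = 12),
                                   n_subjects = 11,
                                   duration_seconds = 345,
                                   n_voxels_per_region = 20,
                                   n_repetitions = 2,
                                   noise_sd = 1.6) {
  tr <- if (isTRUE(all.equal(config$tr_seconds, 1.8))) 1.5 else config$tr_seconds
  long <- trw_spec[trw_spec > 0]
  if (length(long) && any(long < tr)) {
    stop("generate_movie_dataset: long-TRW windows must be >= tr_seconds")
  }
  stim <- generate_stimulus_course(duration_seconds, seed = config$seed)
  scram <- scramble_stimulus(stim, seed = config$seed)
  clean <- list(
    intact = lapply(trw_spec, trw_response, stimulus = stim, tr_seconds = tr),
    scrambled = lapply(trw_spec, trw_response, stimulus = scram, tr_seconds = tr)
  )
  responses <- with_seed(substream_seed(config$seed, "movie"), {
    lapply(clean, function(cond) {
      lapply(seq_len(n_subjects), function(s) {
        lapply(cond, function(sig) {
          reps <- lapply(seq_len(n_repetitions), function(r) {
            matrix(rep(sig, each = n_voxels_per_region), n_voxels_per_region) +
              noise_sd * matrix(stats::rnorm(n_voxels_per_region * length(sig)),
                                n_voxels_per_region)
          })
          reps
        })
      })
    })
  })
  truth <- sim_truth(
    network_assignment = stats::setNames(names(trw_spec), names(trw_spec)),
    trw_label = stats::setNames(ifelse(trw_spec > 0, "long", "short"),
                                names(trw_spec))
  )
  structure(
    list(responses = responses, clean = clean, stimulus = stim,
         scrambled_stimulus = scram, tr_seconds = tr,
         trw_spec = trw_spec, noise_sd = noise_sd, truth = truth,
         n_subjects = n_subjects),
    class = "movie_dataset")
}

# ---------------------------------------------------------------------------
# Block-design simulation

#' Generate a block-design task dataset with planted effect sizes
#'
#' Voxel series are `planted_betas` times HRF-convolved condition
#' square waves, plus quadratic drift and white noise.
#'
#' @param config a [sim_config()].
#' @param block_table data frame with `onset`, `duration` (seconds) and
#'   `condition`; blocks of the same condition must not overlap.
#' @param planted_betas matrix voxels x conditions (columns named by
#'   condition).
#' @param noise_sd noise SD (default `config$noise_sd`).
#' @param drift_sd amplitude of random polynomial drift.
#' @param hemisphere per-voxel hemisphere labels (default all `"R"`).
#' @return list of class `block_dataset`: `subjects` (list of
#'   [subject_dataset()]), `design` (the [build_design()] result),
#'   `block_table`, `truth`.
#' @export
generate_block_design_dataset <- function(config, block_table, planted_betas,
                                          noise_sd = config$noise_sd,
                                          drift_sd = 0.3,
                                          hemisphere = NULL) {
  planted_betas <- as.matrix(planted_betas)
  conds <- sort(unique(as.character(block_table$condition)))
  if (is.null(colnames(planted_betas))) colnames(planted_betas) <- conds
  stopifnot(all(conds %in% colnames(planted_betas)))
  for (cc in conds) {
    b <- block_table[block_table$condition == cc, , drop = FALSE]
    b <- b[order(b$onset), , drop = FALSE]
    if (nrow(b) > 1 && any(utils::head(b$onset + b$duration, -1) >
                           utils::tail(b$onset, -1) + 1e-9)) {
      stop(sprintf("overlapping blocks for condition '%s'", cc))
    }
  }
  des <- build_design(block_table, hrf_spec = "double-gamma",
                      tr = config$tr_seconds, n_timepoints = config$n_timepoints)
  xc <- des$matrix[, des$condition_columns, drop = FALSE]
  n_vox <- nrow(planted_betas)
  if (is.null(hemisphere)) hemisphere <- rep("R", n_vox)
  tt <- seq_len(config$n_timepoints) / config$n_timepoints
  coords <- cbind(seq_len(n_vox) * 2, -28, 4)  # synthetic line of voxels
  subjects <- with_seed(substream_seed(config$seed, "block"), {
    lapply(seq_len(config$n_subjects), function(s) {
      drift <- outer(stats::rnorm(n_vox, 0, drift_sd), tt) +
        outer(stats::rnorm(n_vox, 0, drift_sd), tt^2)
      y <- planted_betas[, conds, drop = FALSE] %*%
        t(xc[, conds, drop = FALSE]) + drift +
        noise_sd * matrix(stats::rnorm(n_vox * config$n_timepoints), n_vox)
      subject_dataset(y, config$tr_seconds, coords, hemisphere,
                      subject_id = sprintf("S%02d", s))
    })
  })
  truth <- sim_truth(network_assignment = character(0),
                     planted_betas = planted_betas)
  structure(list(subjects = subjects, design = des, block_table = block_table,
                 truth = truth, config = config),
            class = "block_dataset")
}

#' Standard laterality/attention block table
#'
#' 16 s stimulation blocks interleaved with 16 s fixation baseline, cycling
#' through contralateral stimulation under central fixation, ipsilateral
#' stimulation under central fixation, and contralateral stimulation under
#' covert attention; each condition appears `n_cycles` times.
#'
#' @param n_cycles blocks per condition.
#' @param block_seconds block duration (default 16).
#' @return data frame with `onset`, `duration`, `condition`.
#' @export
laterality_block_table <- function(n_cycles = 4, block_seconds = 16) {
  conds <- c("stim_contra", "stim_ipsi", "att_contra")
  onsets <- numeric(0); cond <- character(0)
  t0 <- block_seconds  # lead-in fixation period
  for (i in seq_len(n_cycles)) {
    for (cc in conds) {
      onsets <- c(onsets, t0); cond <- c(cond, cc)
      t0 <- t0 + 2 * block_seconds  # block + fixation gap
    }
  }
  data.frame(onset = onsets, duration = block_seconds, condition = cond)
}

#' Generate the default synthetic laterality/attention dataset
#'
#' Plants the reference tuning pattern: "ventral" voxels respond strongly
#' to contralateral stimulation with little ipsilateral response or
#' attentional modulation; "dorsal" voxels respond weakly and similarly to
#' both hemifields but gain from covert attention.
#'
#' @param config a [sim_config()]; `n_subjects` is typically 5 and
#'   `tr_seconds` 2.0 for this protocol.
#' @param n_voxels_per_compartment voxels per planted compartment.
#' @return a `block_dataset` whose truth carries a `compartment` attribute.
#' @export
generate_laterality_dataset <- function(config = sim_config(n_subjects = 5,
                                                            tr_seconds = 2.0,
                                                            n_timepoints = 208),
                                        n_voxels_per_compartment = 30) {
  bt <- laterality_block_table()
  need <- max(bt$onset + bt$duration) / config$tr_seconds + 8
  if (config$n_timepoints < need) {
    stop("generate_laterality_dataset: run too short for the block table")
  }
  nv <- n_voxels_per_compartment
  betas <- rbind(
    cbind(stim_contra = rep(1.0, nv), stim_ipsi = rep(0.25, nv),
          att_contra = rep(1.1, nv)),                       # ventral
    cbind(stim_contra = rep(0.35, nv), stim_ipsi = rep(0.30, nv),
          att_contra = rep(0.80, nv))                       # dorsal
  )
  ds <- generate_block_design_dataset(config, bt, betas)
  ds$compartment <- rep(c("ventral", "dorsal"), each = nv)
  ds
}

#' Generate a synthetic category-localizer dataset
#'
#' Blocks of face and scene stimulation; a compact face-selective cluster is
#' planted in the posterior-medial octant of a small right-hemisphere
#' thalamic lattice (face beta exceeding scene beta), all other voxels have
#' equal betas.
#'
#' @param config a [sim_config()] (16 subjects typical).
#' @param grid integer length-3 lattice dims.
#' @param face_effect planted face-minus-scene beta inside the cluster.
#' @return a `block_dataset` with voxel coordinates on the lattice and a
#'   logical `truth$planted_cluster` vector.
#' @export
generate_category_dataset <- function(config = sim_config(n_subjects = 16,
                                                          tr_seconds = 2.0,
                                                          n_timepoints = 160),
                                      grid = c(6, 6, 6),
                                      face_effect = 0.8) {
  bt <- {
    onsets <- seq(16, by = 32, length.out = 8)
    data.frame(onset = onsets, duration = 16,
               condition = rep(c("faces", "scenes"), 4))
  }
  coords <- as.matrix(expand.grid(x = seq_len(grid[1]) * 2 + 6,
                                  y = seq_len(grid[2]) * 2 - 36,
                                  z = seq_len(grid[3]) * 2 - 6))
  n_vox <- nrow(coords)
  pm <- coords[, 2] <= stats::median(coords[, 2]) &   # posterior
    coords[, 1] <= stats::median(coords[, 1]) &        # medial (small |x|, RH)
    coords[, 3] <= stats::median(coords[, 3])          # ventral
  ctr <- colMeans(coords[pm, , drop = FALSE])
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  cluster <- pm & d2 <= sort(d2[pm])[min(sum(pm), 8)]
  betas <- cbind(faces = ifelse(cluster, 0.6 + face_effect, 0.6),
                 scenes = rep(0.6, n_vox))
  ds <- generate_block_design_dataset(config, bt, betas)
  for (s in seq_along(ds$subjects)) ds$subjects[[s]]$voxel_coords_mm <- coords
  ds$truth$planted_cluster <- cluster
  ds$coords <- coords
  ds
}

# ---------------------------------------------------------------------------
# Dorsal peak-coordinate simulation (fine-scale structure)

#' Generate synthetic per-area connectivity-peak coordinates in the dorsal thalamus
#'
#' Plants three groups of peak locations emulating the fine-scale structure
#' of fronto-parietal coupling: a dorsal-attention-like group (IPS1-4,
#' SPL1, FEF, IFS), a tool-network-like group (IPS5, antPPC, latTemp) and a
#' default-mode-like group (IPL, PreC, latPPC, medPPC). Group centers are
#' several millimetres apart; within-group spread is sub-millimetre, small
#' relative to the between-group separation.
#'
#' @param seed integer seed.
#' @param spread_mm within-group SD per axis (default 0.5, sub-millimetre as
#'   for functionally matched area pairs).
#' @return data frame with `area`, `group`, `x`, `y`, `z`.
#' @export
generate_dorsal_peaks <- function(seed = 1L, spread_mm = 0.5) {
  groups <- list(
    attention = c("IPS1", "IPS2", "IPS3", "IPS4", "SPL1", "FEF", "IFS"),
    tool = c("IPS5", "antPPC", "latTemp"),
    default_mode = c("IPL", "PreC", "latPPC", "medPPC")
  )
  centers <- rbind(attention = c(15, -25, 10),
                   tool = c(9, -31, 13),
                   default_mode = c(6, -24, 6))
  with_seed(substream_seed(seed, "dorsal-peaks"), {
    do.call(rbind, lapply(names(groups), function(g) {
      nm <- groups[[g]]
      n <- length(nm)
      xyz <- sweep(matrix(stats::rnorm(3 * n, 0, spread_mm), n, 3), 2,
                   centers[g, ], "+")
      data.frame(area = nm, group = g,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }))
  })
}
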