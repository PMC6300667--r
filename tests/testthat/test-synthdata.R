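small_cfg <- function(...) {
  defaults <- list(n_subjects = 2, voxel_dims = c(3, 3, 4), n_timepoints = 60,
                   seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("simulation config rejects inconsistent parameters", {
  expect_error(sim_config(within_network_corr = 0.1, between_network_corr = 0.4),
               "must exceed")
  expect_error(sim_config(between_network_corr = -0.05), "0 <= between")
  expect_error(sim_config(network_floor = 1.5), "network_floor")
  expect_error(sim_config(noise_sd = -1), "negative noise")
  expect_error(sim_config(n_timepoints = 2), "time axis")
})

test_that("latent covariance is symmetric, unit-diagonal, PSD, and network-structured", {
  cfg <- sim_config()
  sig <- latent_covariance(cfg)
  expect_true(isSymmetric(sig))
  expect_equal(unname(diag(sig)), rep(1, nrow(sig)))
  expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  idx <- area_hemi_idx(cfg$areas, "R")
  net <- cfg$areas$network[idx]
  same <- outer(net, net, "==") & upper.tri(sig)
  diff <- outer(net, net, "!=") & upper.tri(sig)
  floor_corr <- cfg$between_network_corr +
    cfg$network_floor * (cfg$within_network_corr - cfg$between_network_corr)
  expect_true(all(sig[same] > floor_corr - 1e-9))
  expect_true(all(abs(sig[diff] - cfg$between_network_corr) < 1e-12))
})

test_that("generators are pure functions of config and seed", {
  cfg <- small_cfg()
  a <- generate_resting_dataset(cfg)
  b <- generate_resting_dataset(cfg)
  expect_identical(a$subjects[[1]]$voxel_series, b$subjects[[1]]$voxel_series)
  expect_identical(a$areas$series, b$areas$series)
  expect_identical(generate_dorsal_peaks(seed = 3), generate_dorsal_peaks(seed = 3))
  expect_false(identical(generate_dorsal_peaks(seed = 3),
                         generate_dorsal_peaks(seed = 4)))
})

test_that("empirical within-network area correlations exceed between-network ones in every seed", {
  for (s in 1:10) {
    rest <- generate_resting_dataset(sim_config(n_subjects = 1, seed = s))
    idx <- area_hemi_idx(rest$areas, "R")
    r <- cor(t(rest$areas$series[[1]][idx, ]))
    net <- rest$areas$network[idx]
    same <- outer(net, net, "==") & upper.tri(r)
    diff <- outer(net, net, "!=") & upper.tri(r)
    expect_gt(mean(r[same]), mean(r[diff]))
  }
})

test_that("noise-free voxels are unit-norm nonnegative mixtures of their compartment's areas", {
  cfg <- small_cfg(noise_sd = 0, area_noise_sd = 0, nuisance_scale = 0)
  rest <- generate_resting_dataset(cfg)
  ds <- rest$subjects[[1]]
  idxR <- area_hemi_idx(rest$areas, "R")
  a_r <- rest$areas$series[[1]][idxR, ]
  vox <- ds$voxel_series[ds$hemisphere == "R", ]
  comp <- rest$truth$voxel_gradient
  vcomp <- comp$compartment[comp$hemisphere == "R"]
  net <- rest$areas$network[idxR]

  # recover the mixing weights by regression on the (noise-free) area series
  x <- t(a_r)
  w <- qr.coef(qr(x), t(vox))
  expect_lt(max(abs(x %*% w - t(vox))), 1e-8)   # exact linear combination
  for (v in seq_len(nrow(vox))) {
    own <- (net == "occipito-temporal") == (vcomp[v] == "ventral")
    expect_lt(max(abs(w[!own, v])), 1e-8)       # other compartment unused
    expect_gte(min(w[own, v]), -1e-8)           # nonnegative weights
    expect_equal(sum(w[, v]^2), 1, tolerance = 1e-8)
  }
})

test_that("generated area correlation matrices are symmetric with unit diagonal", {
  rest <- generate_resting_dataset(small_cfg())
  idx <- area_hemi_idx(rest$areas, "L")
  p <- area_profile(rest$areas$series[[2]][idx, ])
  expect_true(isSymmetric(p))
  expect_equal(unname(diag(p)), rep(1, nrow(p)))
  expect_true(all(p >= -1 - 1e-12 & p <= 1 + 1e-12))
})

test_that("stimulus scrambling permutes contiguous segments and preserves the sample multiset", {
  stim <- generate_stimulus_course(60, seed = 5)
  scr <- scramble_stimulus(stim, seed = 5)
  expect_equal(sort(scr$values), sort(stim$values))
  expect_identical(scr$values, scramble_stimulus(stim, seed = 5)$values)
  expect_false(identical(scr$values, stim$values))

  lens <- (scr$segments$end - scr$segments$start + 1) * stim$dt
  interior <- head(lens, -1)
  expect_true(all(interior >= 0.5 - 1e-9 & interior <= 1.6 + stim$dt + 1e-9))
  expect_equal(sum(scr$segments$end - scr$segments$start + 1), length(stim$values))
})

test_that("a single-segment scramble is the identity", {
  stim <- generate_stimulus_course(1, seed = 2)
  scr <- scramble_stimulus(stim, segment_min = 1, segment_max = 1, seed = 1)
  expect_equal(scr$values, stim$values)
  expect_error(scramble_stimulus(stim, segment_min = 0, segment_max = 1),
               "positive")
  expect_error(scramble_stimulus(stim, segment_min = 2, segment_max = 5),
               "shorter")
})

test_that("short-window responses commute with scrambling; long-window responses do not", {
  stim <- generate_stimulus_course(30, seed = 11)
  scr <- scramble_stimulus(stim, seed = 11)
  # sampling at the fine grid's own rate makes the short-TRW mapping pointwise
  expect_equal(trw_response(scr, 0, tr_seconds = stim$dt), scr$values)
  long_intact <- trw_response(stim, 1.0, tr_seconds = stim$dt)
  long_scr <- trw_response(scr, 1.0, tr_seconds = stim$dt)
  expect_false(isTRUE(all.equal(sort(long_scr), sort(long_intact))))
})

test_that("a one-sample window degenerates to the instantaneous response", {
  stim <- generate_stimulus_course(20, seed = 4)
  expect_equal(trw_response(stim, stim$dt, 1.5), trw_response(stim, 0, 1.5))
  expect_error(trw_response(stim, 1000, 1.5), "longer than run")
})

test_that("noise-free movie responses are identical across subjects", {
  mv <- generate_movie_dataset(small_cfg(), n_subjects = 3,
                               duration_seconds = 60, noise_sd = 0)
  for (cond in c("intact", "scrambled")) {
    for (rg in names(mv$trw_spec)) {
      expect_equal(mv$responses[[cond]][[1]][[rg]][[1]],
                   mv$responses[[cond]][[2]][[rg]][[1]])
      expect_equal(mv$responses[[cond]][[2]][[rg]][[1]],
                   mv$responses[[cond]][[3]][[rg]][[2]])
    }
  }
})

test_that("block-design generator rejects overlapping blocks and honors zero noise", {
  cfg <- small_cfg(n_timepoints = 100, tr_seconds = 2)
  bad <- data.frame(onset = c(10, 18), duration = 16, condition = "a")
  expect_error(generate_block_design_dataset(cfg, bad, matrix(1, 4, 1,
               dimnames = list(NULL, "a"))), "overlapping")

  bt <- data.frame(onset = c(16, 80), duration = 16, condition = "a")
  zero <- generate_block_design_dataset(cfg, bt,
            matrix(0, 4, 1, dimnames = list(NULL, "a")),
            noise_sd = 0, drift_sd = 0)
  y <- zero$subjects[[1]]$voxel_series
  expect_true(all(y == y[1, 1]))
})

test_that("noise-free planted betas round-trip through the GLM fit", {
  cfg <- small_cfg(n_subjects = 1, n_timepoints = 120, tr_seconds = 2)
  bt <- data.frame(onset = c(16, 80, 150), duration = 16,
                   condition = c("a", "b", "a"))
  planted <- cbind(a = c(1, 0.5, -0.3), b = c(0, 1, 2))
  ds <- generate_block_design_dataset(cfg, bt, planted,
                                      noise_sd = 0, drift_sd = 0)
  fit <- fit_glm(ds$subjects[[1]], ds$design)
  expect_equal(unname(fit$betas[, c("a", "b")]), unname(planted),
               tolerance = 1e-8)
})

test_that("the laterality protocol plants opposite ventral/dorsal tuning", {
  ds <- generate_laterality_dataset()
  b <- ds$truth$planted_betas
  v <- ds$compartment == "ventral"
  expect_gt(mean(b[v, "stim_contra"] - b[v, "stim_ipsi"]),
            mean(b[!v, "stim_contra"] - b[!v, "stim_ipsi"]))
  expect_gt(mean(b[!v, "att_contra"] - b[!v, "stim_contra"]),
            mean(b[v, "att_contra"] - b[v, "stim_contra"]))
})

test_that("dorsal peak generator plants three tight, well-separated groups", {
  pk <- generate_dorsal_peaks(seed = 1)
  expect_setequal(unique(pk$group), c("attention", "tool", "default_mode"))
  expect_equal(nrow(pk), 14)
  xyz <- as.matrix(pk[, c("x", "y", "z")])
  centers <- do.call(rbind, lapply(split(as.data.frame(xyz), pk$group), colMeans))
  within <- max(sapply(split(as.data.frame(xyz), pk$group), function(g) {
    max(dist(as.matrix(g)))
  }))
  expect_gt(min(dist(centers)), within)
})
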