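test_that("the double-gamma response to a brief block peaks 4-8 s after onset", {
  bt <- data.frame(onset = 20, duration = 2, condition = "a")
  des <- build_design(bt, tr = 1, n_timepoints = 80)
  col <- des$matrix[, "a"]
  expect_equal(des$condition_columns, "a")
  peak_t <- which.max(col) - 1   # TR 1 s, sample 1 is t = 0
  expect_gte(peak_t, 24)
  expect_lte(peak_t, 28)
  h <- hrf_double_gamma(seq(0, 30, by = 0.1))
  expect_equal(max(h), 1)
  expect_lt(min(h), 0)   # undershoot present
})

test_that("a delta-kernel design reproduces the block square wave", {
  bt <- data.frame(onset = 0, duration = 16, condition = "stim")
  des <- build_design(bt, hrf_spec = "delta", tr = 2, n_timepoints = 20)
  expect_equal(unname(des$matrix[, "stim"]), c(rep(1, 8), rep(0, 12)))
})

test_that("designs without blocks contain only baseline and drift columns", {
  des <- build_design(data.frame(onset = numeric(0), duration = numeric(0),
                                 condition = character(0)),
                      tr = 2, n_timepoints = 30)
  expect_identical(colnames(des$matrix), c("baseline", "drift"))
  expect_error(build_design(data.frame(onset = 50, duration = 20,
                                       condition = "a"),
                            tr = 2, n_timepoints = 30), "past end")
  expect_error(build_design(data.frame(onset = 0, duration = 16,
                                       condition = "a"),
                            tr = 2, n_timepoints = 30,
                            nuisance = cbind(rep(1, 30))), "rank deficient")
})

test_that("the GLM fit matches the normal-equations oracle and recovers noiseless betas", {
  # hand 5-sample, 2-column case
  x <- cbind(c(1, 0, 1, 0, 1), c(0.2, 0.4, 0.6, 0.8, 1.0))
  y <- matrix(c(1.5, 0.3, 2.1, 0.9, 3.0), 1)
  des <- list(matrix = cbind(x, baseline = 1), condition_columns = c("c1", "c2"),
              tr_seconds = 1, n_timepoints = 5)
  colnames(des$matrix) <- c("c1", "c2", "baseline")
  class(des) <- "design_matrix"
  fit <- fit_glm(y, des)
  beta_oracle <- solve(t(des$matrix) %*% des$matrix, t(des$matrix) %*% t(y))
  expect_equal(as.numeric(fit$betas), as.numeric(beta_oracle), tolerance = 1e-10)

  # noiseless spanned data
  bt <- data.frame(onset = c(10, 60), duration = 16, condition = c("a", "b"))
  des2 <- build_design(bt, tr = 2, n_timepoints = 60)
  truth <- c(a = 2, b = -1)
  y2 <- matrix(des2$matrix[, c("a", "b")] %*% truth + 0.5, 1, byrow = TRUE)
  fit2 <- fit_glm(y2, des2, contrasts = list(avb = c(1, -1)))
  expect_equal(unname(fit2$betas[, c("a", "b")]), unname(truth), tolerance = 1e-8)
  expect_equal(unname(fit2$contrasts$avb$value), 3, tolerance = 1e-8)

  expect_error(fit_glm(matrix(rnorm(10), 1), des2), "timepoints")
})

test_that("contrast tests on pure noise hold their nominal false-positive rate", {
  bt <- data.frame(onset = seq(10, 170, by = 40), duration = 16,
                   condition = rep(c("a", "b"), length.out = 5))
  des <- build_design(bt, tr = 2, n_timepoints = 100)
  set.seed(21)
  y <- matrix(rnorm(2000 * 100), 2000)
  fit <- fit_glm(y, des, contrasts = list(d = c(1, -1)))
  expect_lt(abs(mean(fit$contrasts$d$p < 0.05) - 0.05), 0.02)
})

test_that("the tuning index is the standardized mean difference with its symmetries", {
  expect_equal(dprime_index(1, 2, 1, 3), 0)
  expect_equal(dprime_index(2, 2, 0, 2), 1)
  expect_equal(dprime_index(3, 1, 1, 2), -dprime_index(1, 2, 3, 1))
  c0 <- dprime_index(1.3, 0.7, 0.4, 1.1)
  expect_equal(dprime_index(13, 7, 4, 11), c0)
  expect_error(dprime_index(1, 0, 2, 0), "undefined")
})

test_that("block response windows track the lagged plateau of each condition", {
  bt <- data.frame(onset = c(10, 50), duration = 10, condition = "a")
  tr <- 2
  y <- rep(0, 50)
  # plant the value 3 exactly in the 6 s lagged windows
  for (o in bt$onset) y[(floor((o + 6) / tr) + 1):ceiling((o + 6 + 10) / tr)] <- 3
  st <- block_response_stats(y, bt, "a", tr)
  expect_equal(st$mu, 3)
  expect_equal(st$sd, 0)
  expect_error(block_response_stats(y, bt, "zzz", tr), "no blocks")
})

test_that("planted laterality and attention effects dissociate by compartment", {
  ds <- generate_laterality_dataset()
  ti <- tuning_indices(ds)
  v <- ds$compartment == "ventral"
  expect_gt(mean(ti$laterality[v, ]), mean(ti$laterality[!v, ]))
  expect_gt(mean(ti$attention[!v, ]), mean(ti$attention[v, ]))
  expect_gt(mean(ti$laterality[v, ]), 1)   # strong contralateral preference
})

test_that("precision weighting matches its closed form", {
  b <- matrix(c(1, 2, 3, 0.5, 1.5, 2.5), 2, 3, byrow = TRUE)
  v <- matrix(c(1, 4, 2, 1, 1, 1), 2, 3, byrow = TRUE)
  g <- precision_weighted_group(b, v)
  expect_equal(g$z[1], (1 / 1 + 2 / 4 + 3 / 2) / sqrt(1 + 1 / 4 + 1 / 2))
  expect_equal(g$z[2], sum(b[2, ]) / sqrt(3))
  expect_equal(g$p, 2 * pnorm(-abs(g$z)))
})

test_that("leave-one-out ROI definition never uses the held-out subject", {
  # 3 subjects on a 4x4x4 lattice; cluster of positive contrast in a corner
  coords <- as.matrix(expand.grid(x = 1:4 * 2, y = 1:4 * 2, z = 1:4 * 2))
  nv <- nrow(coords)
  cl <- coords[, 1] <= 4 & coords[, 2] <= 4 & coords[, 3] <= 4
  base <- ifelse(cl, 5, 0)
  vals <- cbind(base, base, -0.4 * base)    # subject 3 responds negatively
  vars <- matrix(0.01, nv, 3)
  betas <- list(face = vals, scene = matrix(0, nv, 3))
  out <- loo_category_roi(vals, vars, betas, coords,
                          restrict = rep(TRUE, nv))
  f3 <- out[out$subject == 3 & out$condition == "face", ]
  # subject 3's ROI comes from the two concordant subjects, so it reads out
  # subject 3's own (negative) values inside the planted cluster
  expect_equal(f3$roi_size, sum(cl))
  expect_lt(f3$mean_beta, 0)

  # identical subjects give identical ROIs in every fold
  same <- cbind(base, base, base)
  out2 <- loo_category_roi(same, vars, betas, coords, restrict = rep(TRUE, nv))
  expect_equal(length(unique(out2$roi_size)), 1)

  expect_error(loo_category_roi(vals[, 1:2], vars[, 1:2],
                                lapply(betas, function(b) b[, 1:2]), coords),
               "at least 3")
})

test_that("planted category clusters are recovered by held-out readouts across seeds", {
  hits <- 0L
  folds <- 0L
  for (s in 1:10) {
    ds <- generate_category_dataset(sim_config(n_subjects = 16, tr_seconds = 2,
                                               n_timepoints = 160, seed = s))
    nsub <- length(ds$subjects)
    vals <- vars <- matrix(0, nrow(ds$coords), nsub)
    bf <- bs <- matrix(0, nrow(ds$coords), nsub)
    for (i in seq_len(nsub)) {
      fit <- fit_glm(ds$subjects[[i]], ds$design,
                     contrasts = list(fvs = c(1, -1)))
      vals[, i] <- fit$contrasts$fvs$value
      vars[, i] <- (fit$contrasts$fvs$value / fit$contrasts$fvs$t)^2
      bf[, i] <- fit$betas[, "faces"]
      bs[, i] <- fit$betas[, "scenes"]
    }
    out <- loo_category_roi(vals, vars, list(face = bf, scene = bs), ds$coords)
    d <- out$mean_beta[out$condition == "face"] -
      out$mean_beta[out$condition == "scene"]
    hits <- hits + sum(d > 0)
    folds <- folds + length(d)
  }
  expect_gte(hits / folds, 0.9)
})

test_that("group statistics match hand Benjamini-Hochberg cases and flag degeneracies", {
  # 10 identical p-values at 0.01 under q = 0.05: all rejected
  set.seed(5)
  vals <- matrix(rnorm(10 * 8, mean = 1.2, sd = 1), 10, 8)
  gs <- group_stats(vals)
  expect_true(all(c("estimate", "statistic", "p", "q", "cohen_d",
                    "significant") %in% names(gs)))
  expect_equal(gs$q, oracle_bh_adjust(gs$p), tolerance = 1e-12)

  one <- group_stats(matrix(rnorm(6, 3), 1, 6))
  expect_equal(one$q, one$p)   # BH with m = 1

  const <- group_stats(matrix(1, 2, 5))
  expect_true(all(is.na(const$p)))
  expect_false(any(const$significant))

  w <- group_stats(matrix(c(-2, -1, 1, 2, -0.5, 0.5), 1), test = "wilcoxon")
  expect_gt(w$p, 0.9)   # symmetric data: direction-free

  fz <- group_stats(matrix(c(0.3, 0.5, 0.4, 0.45), 1), fisher = TRUE)
  expect_equal(fz$estimate, mean(atanh(c(0.3, 0.5, 0.4, 0.45))))
  expect_error(group_stats(matrix(1, 2, 1)), "at least 2")
})
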