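test_that("map similarity is Pearson between vectorized maps", {
  m <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(3, 1, 2))
  s <- map_similarity(m)
  expect_equal(s["A", "B"], 1)
  expect_equal(s["A", "C"], oracle_pearson(m[, "A"], m[, "C"]),
               tolerance = 1e-12)
  m2 <- cbind(A = c(1, 2, 3), B = c(2, 2, 2))
  expect_error(map_similarity(m2), "constant map for area\\(s\\): B")
})

test_that("classical MDS reproduces Euclidean geometry and matches the double-centering oracle", {
  d2 <- matrix(c(0, 3, 3, 0), 2)
  pts <- classical_mds(d2)
  expect_equal(as.numeric(dist(pts)), 3, tolerance = 1e-10)

  line <- as.matrix(dist(cbind(c(0, 1, 2.5, 4, 7))))
  emb <- classical_mds(line)
  expect_equal(as.matrix(dist(emb)), unname(line), tolerance = 1e-8,
               ignore_attr = TRUE)
  # first axis carries at least as much variance as the second
  expect_gte(var(emb[, 1]), var(emb[, 2]))

  expect_equal(classical_mds(matrix(0, 4, 4)), matrix(0, 4, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(14)
  pts8 <- matrix(rnorm(16), 8, 2)
  d8 <- as.matrix(dist(pts8))
  expect_equal_up_to_sign(classical_mds(d8), oracle_mds(d8), tol = 1e-6)

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2)), "isSymmetric")
})

test_that("dissimilarity rows are Euclidean distances between similarity rows", {
  s <- cor(matrix(rnorm(50), 10, 5))
  d <- similarity_to_dissimilarity(s)
  expect_equal(d[1, 2], sqrt(sum((s[1, ] - s[2, ])^2)), tolerance = 1e-12)
  expect_true(all(diag(d) == 0))
})

test_that("spectral modularity finds planted blocks and stops on uniform structure", {
  # two disconnected cliques
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1
  diag(w) <- 0
  rownames(w) <- colnames(w) <- letters[1:6]
  cl <- spectral_clusters(w)
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)

  # complete uniform graph: indivisible
  u <- matrix(1, 5, 5); diag(u) <- 0
  expect_equal(spectral_clusters(u)$n_clusters, 1)

  expect_error(spectral_clusters(matrix(0, 0, 0)), "empty")
  expect_error(spectral_clusters(matrix(0, 3, 3)), "no edges")
})

test_that("planted two-block similarity is recovered in nearly every seed", {
  hits <- sapply(1:20, function(s) {
    set.seed(s)
    truth <- rep(1:2, each = 6)
    w <- matrix(0.1, 12, 12)
    w[truth == 1, truth == 1] <- 0.6
    w[truth == 2, truth == 2] <- 0.6
    w <- w + matrix(rnorm(144, 0, 0.05), 12)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    cl <- spectral_clusters(w)
    mclust::adjustedRandIndex(cl$labels, truth) == 1
  })
  expect_gte(sum(hits), 19)
})

test_that("clustering is invariant to node relabeling and beats the greedy igraph baseline", {
  set.seed(15)
  truth <- rep(1:2, each = 5)
  w <- matrix(0.1, 10, 10)
  w[truth == 1, truth == 1] <- 0.5
  w[truth == 2, truth == 2] <- 0.5
  w <- w + matrix(rnorm(100, 0, 0.03), 10)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  rownames(w) <- colnames(w) <- paste0("n", 1:10)

  cl <- spectral_clusters(w)
  perm <- sample(10)
  clp <- spectral_clusters(w[perm, perm])
  expect_equal(mclust::adjustedRandIndex(cl$labels[perm], clp$labels), 1)

  wz <- w; wz[wz < 0] <- 0
  ig <- igraph::graph_from_adjacency_matrix(wz, mode = "undirected",
                                            weighted = TRUE)
  mem <- igraph::membership(igraph::cluster_leading_eigen(ig))
  q_ig <- igraph::modularity(ig, mem, weights = igraph::E(ig)$weight)
  expect_gte(cl$modularity + 1e-9, q_ig)
  # and our modularity value agrees with igraph's for our own partition
  expect_equal(cl$modularity,
               igraph::modularity(ig, cl$labels, weights = igraph::E(ig)$weight),
               tolerance = 1e-10)
})

test_that("Procrustes alignment matches brute-force and vegan oracles", {
  set.seed(16)
  x <- matrix(rnorm(16), 8, 2)
  # exact similarity transform: SSE 0
  th <- 0.7
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  y <- 2.5 * x %*% r + matrix(rep(c(3, -1), each = 8), 8)
  f <- procrustes_fit(x, y)
  expect_lt(f$sse, 1e-12)
  expect_equal(f$aligned, y, tolerance = 1e-8)

  same <- procrustes_fit(x, x)
  expect_lt(same$sse, 1e-12)
  expect_equal(same$rotation, diag(2), tolerance = 1e-8)
  expect_equal(same$scale, 1, tolerance = 1e-10)

  # 4-point hand case against the rotation-grid oracle
  a <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  b <- matrix(c(0.1, -0.2, 1.3, 0.5, 0.8, 1.6, -0.4, 0.9), 4, 2, byrow = TRUE)
  expect_equal(procrustes_fit(a, b)$sse, oracle_procrustes_sse(a, b),
               tolerance = 1e-6)

  # vegan's symmetric Procrustes statistic is the same normalized SSE
  z <- matrix(rnorm(20), 10, 2)
  zz <- matrix(rnorm(20), 10, 2)
  expect_equal(procrustes_fit(z, zz)$sse,
               vegan::procrustes(zz, z, symmetric = TRUE)$ss,
               tolerance = 1e-10)

  expect_error(procrustes_fit(x[1, , drop = FALSE], x[1, , drop = FALSE]),
               "at least 2")
})

test_that("reflections are inside the allowed transform class", {
  x <- matrix(rnorm(12), 6, 2)
  y <- x %*% diag(c(1, -1))
  expect_lt(procrustes_fit(x, y)$sse, 1e-12)
})

test_that("the MDS permutation null matches exhaustive enumeration on 3 points", {
  x <- matrix(c(0, 0, 2, 0, 1, 2), 3, 2, byrow = TRUE)
  y <- matrix(c(0.1, 0, 2.2, 0.3, 0.9, 1.8), 3, 2, byrow = TRUE)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  exact <- sort(unique(round(sapply(perms, function(p) {
    procrustes_fit(x[p, ], y)$sse
  }), 12)))
  out <- permutation_test_mds(x, y, n_perm = 300, seed = 2)
  expect_true(all(round(out$null_sse, 12) %in% exact))
  expect_equal(out$observed_sse, procrustes_fit(x, y)$sse)
  expect_equal(out$percentile, mean(out$null_sse <= out$observed_sse))

  # determinism
  out2 <- permutation_test_mds(x, y, n_perm = 300, seed = 2)
  expect_identical(out$null_sse, out2$null_sse)
})

test_that("matched configurations sit at the bottom of the global permutation null", {
  set.seed(17)
  x <- matrix(rnorm(24), 12, 2)
  out <- permutation_test_mds(x, x, n_perm = 200, seed = 1)
  expect_equal(out$observed_sse, 0, tolerance = 1e-12)
  expect_lt(out$p, 0.05)
  expect_equal(out$percentile, 0)
})

test_that("within-cluster permutations only shuffle inside clusters", {
  set.seed(18)
  # cluster members coincide, so within-cluster shuffles are exact no-ops
  x <- rbind(matrix(c(0, 0), 5, 2, byrow = TRUE),
             matrix(c(3, 1), 5, 2, byrow = TRUE))
  y <- matrix(rnorm(20), 10, 2)
  clusters <- rep(1:2, each = 5)
  wc <- permutation_test_mds(x, y, n_perm = 50, mode = "within_cluster",
                             clusters = clusters, seed = 4)
  expect_true(all(abs(wc$null_sse - wc$observed_sse) < 1e-12))
  gl <- permutation_test_mds(x, y, n_perm = 50, mode = "global", seed = 4)
  expect_gt(max(abs(gl$null_sse - gl$observed_sse)), 1e-6)
  expect_error(permutation_test_mds(x, y, mode = "within_cluster"),
               "clusters required")
  expect_warning(permutation_test_mds(x, y, n_perm = 10,
                                      mode = "within_cluster",
                                      clusters = 1:10, seed = 1),
                 "singleton")
})

test_that("Dice overlap follows its formula with symmetry and sharp equality", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(dice_overlap(a, b), 0.5)   # |A|=2, |B|=2, |A n B|=1
  expect_equal(dice_overlap(a, a), 1)
  expect_equal(dice_overlap(a, !a), 0)
  expect_equal(dice_overlap(a, b), dice_overlap(b, a))
  expect_warning(d0 <- dice_overlap(logical(4), logical(4)), "empty")
  expect_equal(d0, 0)

  set.seed(19)
  for (i in 1:20) {
    ma <- runif(30) > 0.5
    mb <- runif(30) > 0.5
    d <- dice_overlap(ma, mb)
    expect_lte(d, 1)
    if (d == 1) expect_identical(ma, mb)
    if (identical(ma, mb) && any(ma)) expect_equal(d, 1)
  }
})

test_that("peak locations break exact ties lexicographically and respect masks", {
  coords <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 1))
  vals <- rep(0, 9)
  vals[5] <- 2
  expect_equal(unname(peak_location(vals, coords)), c(2, 2, 1))

  tie <- rep(0, 9); tie[c(3, 7)] <- 5   # (3,1,1) and (1,3,1)
  expect_equal(unname(peak_location(tie, coords)), c(1, 3, 1))

  msk <- coords[, 1] == 1
  expect_equal(unname(peak_location(vals, coords, mask = msk))[1], 1)
  expect_error(peak_location(rep(NA_real_, 9), coords), "empty map")
})

test_that("bilateral averaging reflects the left peak across the midline", {
  expect_equal(unname(bilateral_average(c(-10, -30, 5), c(12, -30, 5))),
               c(11, -30, 5))
})

test_that("distance relationships stratify pairs by cluster and recover exact linearity", {
  n <- 8
  set.seed(20)
  cd <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dice <- 1 - cd / max(cd)   # exact decreasing linear map
  labels <- rep(1:2, each = 4)
  out <- distance_relationships(cd, dice, labels)
  expect_setequal(out$stratum, c("all", "within_1", "within_2", "between"))
  expect_true(all(abs(out$r + 1) < 1e-10))
  expect_equal(out$n_pairs[out$stratum == "all"], choose(n, 2))
  expect_equal(out$n_pairs[out$stratum == "between"], 16)

  # strata with < 3 pairs are omitted
  out2 <- distance_relationships(cd[1:4, 1:4], dice[1:4, 1:4],
                                 c(1, 1, 2, 2))
  expect_false("within_1" %in% out2$stratum)
})

test_that("peak clustering separates tight groups and collapses coincident points", {
  two <- rbind(matrix(rnorm(9, 0, 0.1), 3), matrix(rnorm(9, 10, 0.1), 3))
  colnames(two) <- c("x", "y", "z")
  cl <- peak_cluster(two)
  expect_equal(cl$n_clusters, 2)

  coin <- matrix(1, 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(peak_cluster(coin)$n_clusters, 1)
  expect_error(peak_cluster(coin[1:2, ]), "at least 3")

  pk <- generate_dorsal_peaks(seed = 1)
  cl3 <- peak_cluster(pk)
  expect_equal(cl3$n_clusters, 3)
  expect_equal(mclust::adjustedRandIndex(cl3$labels, pk$group), 1)
})

test_that("the composed network-structure analysis carries consistent components", {
  cfg <- sim_config(n_subjects = 4, voxel_dims = c(3, 3, 4), n_timepoints = 200,
                    seed = 21)
  rest <- generate_resting_dataset(cfg)
  pp <- preprocess_dataset(rest)
  conn <- connectivity_analysis(pp)
  ns <- network_structure(conn)

  expect_s3_class(ns, "network_structure")
  expect_true(isSymmetric(ns$map_similarity))
  expect_equal(nrow(ns$mds_coords), nrow(ns$map_similarity))
  expect_gte(var(ns$mds_coords[, 1]), var(ns$mds_coords[, 2]))
  expect_equal(sort(unique(names(ns$clusters$labels))),
               sort(rownames(ns$map_similarity)))
  expect_true(all(ns$dice$R >= 0 & ns$dice$R <= 1))
  expect_equal(nrow(ns$peaks), 39)
  expect_true(all(c("area", "x", "y", "z") %in% names(ns$peaks)))

  expect_output(print(ns), "network_structure")
  pdf(NULL)
  expect_silent(plot(ns))
  dev.off()
})
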