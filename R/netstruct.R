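# Network-level structure over connectivity maps: map similarity,
# classical MDS, Procrustes alignment with permutation tests, Newman
# spectral modularity clustering, Dice overlap, peak localization, and
# cortical-distance relationships.

#' Area-by-area similarity of connectivity maps
#'
#' Pearson correlation between the vectorized voxel maps of every pair of
#' cortical areas, computed within hemisphere and then averaged across
#' hemispheres (in Fisher-z space).
#'
#' @param conn a `connectivity_maps` object, or a single voxels x areas
#'   matrix (one hemisphere, e.g. a group mean).
#' @return symmetric areas x areas similarity matrix.
#' @export
map_similarity <- function(conn) {
  sim_one <- function(m) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("map_similarity: constant map for area(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    }
    stats::cor(m)
  }
  if (is.matrix(conn)) return(sim_one(conn))
  hemis <- attr(conn, "hemispheres")
  zs <- lapply(hemis, function(h) {
    m <- conn[[h]]$group$mean
    colnames(m) <- sub("_[LR]$", "", conn[[h]]$area_names)
    fisher_z(sim_one(m))
  })
  z <- Reduce(`+`, zs) / length(zs)
  out <- fisher_z_inv(z)
  diag(out) <- 1
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities and embeds on the top
#' eigenvectors scaled by the square root of their eigenvalues. Negative
#' eigenvalues are truncated. Axes are ordered by decreasing eigenvalue,
#' so the first axis always carries at least as much variance as the
#' second.
#'
#' @param dissimilarity symmetric, zero-diagonal, nonnegative matrix.
#' @param dims embedding dimension (default 2).
#' @return n x dims coordinate matrix (rows named as the input).
#' @export
classical_mds <- function(dissimilarity, dims = 2) {
  d <- as.matrix(dissimilarity)
  stopifnot(isSymmetric(unname(d), tol = 1e-8), all(abs(diag(d)) < 1e-12),
            all(d >= -1e-12))
  n <- nrow(d)
  if (all(d == 0)) {
    pv_log("classical_mds: all-zero dissimilarity; coincident points")
    return(matrix(0, n, dims, dimnames = list(rownames(d), NULL)))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = min(dims, n - 1), eig = TRUE)
  if (any(fit$eig < -1e-8)) {
    pv_log("classical_mds: negative eigenvalues truncated")
  }
  pts <- fit$points
  if (ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  rownames(pts) <- rownames(d)
  pts
}

#' Dissimilarity between similarity-matrix rows
#'
#' Euclidean distances between the rows of an area similarity matrix — the
#' conversion feeding the MDS embedding.
#'
#' @param similarity symmetric similarity matrix.
#' @return dissimilarity matrix.
#' @export
similarity_to_dissimilarity <- function(similarity) {
  as.matrix(stats::dist(similarity))
}

#' Newman spectral modularity clustering with automatic stopping
#'
#' Recursive bisection of a weighted, nonnegative similarity graph along
#' the leading eigenvector of the (generalized) modularity matrix. A group
#' stops splitting when the leading eigenvector has uniform sign or when
#' the split's modularity contribution is not positive, so the cluster
#' count is determined automatically. Negative weights are zeroed by
#' default; set `zero_negative = FALSE` to keep a signed matrix (at the
#' caller's risk).
#'
#' @param w symmetric weight matrix (similarity graph); diagonal ignored.
#' @param zero_negative clip negative weights to 0 (default TRUE).
#' @return object of class `spectral_clustering`: `labels` (integer per
#'   node, named), `n_clusters`, `modularity`.
#' @export
spectral_clusters <- function(w, zero_negative = TRUE) {
  w <- as.matrix(w)
  stopifnot(isSymmetric(unname(w), tol = 1e-8))
  if (zero_negative) w[w < 0] <- 0
  diag(w) <- 0
  n <- nrow(w)
  if (n == 0) stop("spectral_clusters: empty graph")
  k <- rowSums(w)
  m2 <- sum(k)
  if (m2 == 0) stop("spectral_clusters: graph has no edges")
  b <- w - outer(k, k) / m2
  labels <- rep(1L, n)
  next_label <- 2L
  queue <- list(seq_len(n))
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    bg <- b[g, g, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)   # generalized modularity matrix
    eg <- eigen((bg + t(bg)) / 2, symmetric = TRUE)
    v <- eg$vectors[, 1]
    if (eg$values[1] <= 1e-10) next      # no positive leading mode
    s <- ifelse(v >= 0, 1, -1)
    if (all(s == s[1])) next             # sign-uniform: indivisible
    s <- .fine_tune_bisection(bg, s)
    if (all(s == s[1])) next
    dq <- as.numeric(t(s) %*% bg %*% s) / (2 * m2)
    if (dq <= 1e-12) next
    grp2 <- g[s < 0]
    labels[grp2] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(g[s >= 0]), list(grp2))
  }
  labels <- as.integer(factor(labels))
  names(labels) <- rownames(w)
  q <- modularity_value(w, labels)
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 modularity = q),
            class = "spectral_clustering")
}

# Kernighan-Lin-style fine-tuning of a bisection (Newman's refinement
# stage, as in the Brain Connectivity Toolbox): repeatedly sweep over the
# nodes, moving each at most once per sweep in the order of greatest gain
# in s' B s, and keep the best state visited; stop when a sweep yields no
# improvement.
.fine_tune_bisection <- function(bg, s) {
  qval <- function(sv) as.numeric(t(sv) %*% bg %*% sv)
  best <- s
  best_q <- qval(s)
  repeat {
    s_cur <- best
    q_cur <- best_q
    moved <- rep(FALSE, length(s_cur))
    sweep_best <- best_q
    sweep_state <- best
    while (!all(moved)) {
      gains <- vapply(seq_along(s_cur), function(i) {
        if (moved[i]) return(-Inf)
        st <- s_cur
        st[i] <- -st[i]
        qval(st)
      }, numeric(1))
      i <- which.max(gains)
      s_cur[i] <- -s_cur[i]
      moved[i] <- TRUE
      q_cur <- gains[i]
      if (q_cur > sweep_best) {
        sweep_best <- q_cur
        sweep_state <- s_cur
      }
    }
    if (sweep_best > best_q + 1e-12) {
      best_q <- sweep_best
      best <- sweep_state
    } else {
      break
    }
  }
  best
}

#' Modularity of a partition of a weighted graph
#' @param w symmetric nonnegative weight matrix (zero diagonal).
#' @param labels integer membership per node.
#' @return Newman modularity Q.
#' @export
modularity_value <- function(w, labels) {
  k <- rowSums(w)
  m2 <- sum(k)
  b <- w - outer(k, k) / m2
  same <- outer(labels, labels, "==")
  sum(b * same) / m2
}

#' @export
print.spectral_clustering <- function(x, ...) {
  cat(sprintf("spectral clustering: %d clusters, Q = %.3f\n",
              x$n_clusters, x$modularity))
  print(table(x$labels))
  invisible(x)
}

#' Full Procrustes alignment of one configuration to another
#'
#' Optimal translation, rotation (reflections allowed) and isotropic
#' scaling of `source` onto `target`, minimizing the sum of squared
#' errors. The reported SSE is normalized by the target's total variance
#' around its centroid (so 0 is a perfect fit and 1 the fit of a single
#' point at the target centroid).
#'
#' @param source,target n x d coordinate matrices with matched rows.
#' @return list with `aligned`, `sse` (normalized), `rotation`, `scale`,
#'   `translation`.
#' @export
procrustes_fit <- function(source, target) {
  x <- as.matrix(source); y <- as.matrix(target)
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  if (nrow(x) < 2) stop("procrustes_fit: need at least 2 points")
  mx <- colMeans(x); my <- colMeans(y)
  x0 <- sweep(x, 2, mx); y0 <- sweep(y, 2, my)
  ssx <- sum(x0^2); ssy <- sum(y0^2)
  if (ssx == 0 || ssy == 0) {
    return(list(aligned = matrix(rep(my, each = nrow(x)), nrow(x)),
                sse = if (ssy == 0) 0 else 1,
                rotation = diag(ncol(x)), scale = 0, translation = my))
  }
  sv <- svd(crossprod(y0, x0))
  rot <- sv$v %*% t(sv$u)
  traceS <- sum(sv$d)
  scale <- traceS / ssx
  aligned <- scale * x0 %*% rot
  aligned <- sweep(aligned, 2, my, "+")
  sse <- 1 - traceS^2 / (ssx * ssy)
  list(aligned = aligned, sse = max(0, sse), rotation = rot, scale = scale,
       translation = my - scale * as.numeric(mx %*% rot))
}

#' Permutation test for MDS configuration similarity
#'
#' Compares the Procrustes SSE of a subject configuration against the
#' pseudo-group configuration with the null distribution of SSEs obtained
#' by permuting area labels — globally, or only within each cluster.
#'
#' @param subject_coords,group_coords n x 2 matched configurations.
#' @param n_perm permutations (default 1000).
#' @param mode `"global"` or `"within_cluster"`.
#' @param clusters integer labels, required for `within_cluster`.
#' @param seed integer seed.
#' @return list with `observed_sse`, `null_sse`, `percentile` (fraction of
#'   null SSEs at or below the observed), `p` (permutation p value for
#'   observed < null).
#' @export
permutation_test_mds <- function(subject_coords, group_coords, n_perm = 1000,
                                 mode = c("global", "within_cluster"),
                                 clusters = NULL, seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(subject_coords); y <- as.matrix(group_coords)
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  if (mode == "within_cluster") {
    if (is.null(clusters)) stop("permutation_test_mds: clusters required for within_cluster mode")
    if (all(table(clusters) < 2)) {
      warning("permutation_test_mds: all clusters are singletons; degenerate null")
    }
  }
  observed <- procrustes_fit(x, y)$sse
  null_sse <- with_seed(substream_seed(seed, paste0("permute-mds-", mode)), {
    vapply(seq_len(n_perm), function(i) {
      perm <- if (mode == "global") {
        sample.int(n)
      } else {
        p <- seq_len(n)
        for (cl in unique(clusters)) {
          idx <- which(clusters == cl)
          if (length(idx) > 1) p[idx] <- sample(idx)
        }
        p
      }
      procrustes_fit(x[perm, , drop = FALSE], y)$sse
    }, numeric(1))
  })
  list(observed_sse = observed, null_sse = null_sse,
       percentile = mean(null_sse <= observed),
       p = (1 + sum(null_sse <= observed)) / (n_perm + 1))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks give 0 with a warning.
#'
#' @param mask_a,mask_b logical vectors over the same voxel universe.
#' @return numeric in `[0, 1]`.
#' @export
dice_overlap <- function(mask_a, mask_b) {
  stopifnot(length(mask_a) == length(mask_b))
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0) {
    warning("dice_overlap: both masks empty; returning 0")
    return(0)
  }
  2 * sum(mask_a & mask_b) / (a + b)
}

#' Pairwise Dice overlap of thresholded group maps
#'
#' Binarizes each area's group map at `p < p_threshold` (positive effects)
#' and computes Dice overlap for every area pair.
#'
#' @param group result of [group_connectivity()].
#' @param p_threshold significance threshold (default 0.05).
#' @param use_q threshold FDR-adjusted q instead of raw p (default TRUE).
#' @return symmetric areas x areas Dice matrix.
#' @export
dice_matrix <- function(group, p_threshold = 0.05, use_q = TRUE) {
  pm <- if (use_q) group$q else group$p
  masks <- (!is.na(pm)) & pm < p_threshold & group$t > 0
  n_area <- ncol(masks)
  out <- matrix(0, n_area, n_area, dimnames = list(colnames(masks), colnames(masks)))
  for (i in seq_len(n_area)) {
    for (j in i:n_area) {
      out[i, j] <- out[j, i] <- dice_overlap(masks[, i], masks[, j])
    }
  }
  out
}

#' Peak location of a voxel map
#'
#' Coordinate of the maximum value; exact ties are broken by the smallest
#' lexicographic (x, y, z) coordinate.
#'
#' @param values per-voxel map values.
#' @param coords voxels x 3 mm coordinates.
#' @param mask optional logical restriction.
#' @return length-3 named numeric coordinate.
#' @export
peak_location <- function(values, coords, mask = NULL) {
  coords <- as.matrix(coords)
  keep <- if (is.null(mask)) rep(TRUE, length(values)) else mask
  keep <- keep & !is.na(values)
  if (!any(keep)) stop("peak_location: empty map")
  v <- values[keep]
  cc <- coords[keep, , drop = FALSE]
  top <- which(v == max(v))
  if (length(top) > 1) {
    ord <- order(cc[top, 1], cc[top, 2], cc[top, 3])
    top <- top[ord[1]]
    pv_log("peak_location: tie broken lexicographically")
  }
  stats::setNames(as.numeric(cc[top, ]), c("x", "y", "z"))
}

#' Bilateral average of left and right peak coordinates
#'
#' Reflects the left-hemisphere coordinate across the midline (negates x)
#' and averages with the right-hemisphere coordinate.
#'
#' @param left,right length-3 coordinates (x, y, z).
#' @return length-3 averaged coordinate.
#' @export
bilateral_average <- function(left, right) {
  refl <- left
  refl[1] <- -refl[1]
  (refl + right) / 2
}

#' Correlations between cortical distance and coupling-map geometry
#'
#' Correlates upper-triangle cortical distances with Dice overlap (and,
#' optionally, with Euclidean distances between connectivity peaks),
#' overall and stratified by the top-level cluster labels: pairs within
#' each cluster, and between-cluster pairs. Strata with fewer than 3 pairs
#' are omitted.
#'
#' @param cortical_dist areas x areas distance matrix.
#' @param dice areas x areas overlap matrix (or peak-distance matrix).
#' @param cluster_labels integer per area.
#' @return data frame with `stratum`, `r`, `n_pairs`.
#' @export
distance_relationships <- function(cortical_dist, dice, cluster_labels) {
  n <- nrow(cortical_dist)
  stopifnot(nrow(dice) == n, length(cluster_labels) == n)
  ut <- upper.tri(cortical_dist)
  ci <- matrix(cluster_labels, n, n)
  cj <- t(ci)
  strata <- list(all = ut)
  for (cl in sort(unique(cluster_labels))) {
    strata[[paste0("within_", cl)]] <- ut & ci == cl & cj == cl
  }
  strata$between <- ut & ci != cj
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    npair <- sum(sel)
    if (npair < 3) {
      pv_log("distance_relationships: stratum ", nm, " has < 3 pairs; omitted")
      return(NULL)
    }
    data.frame(stratum = nm, r = safe_cor(cortical_dist[sel], dice[sel]),
               n_pairs = npair)
  })
  do.call(rbind, rows)
}

#' Cluster areas by the spatial proximity of their connectivity peaks
#'
#' Builds a Gaussian affinity graph from pairwise Euclidean distances
#' between peak coordinates (bandwidth = median pairwise distance) and
#' applies Newman spectral modularity clustering.
#'
#' @param peaks n x 3 matrix or data frame with `x`, `y`, `z`.
#' @return a `spectral_clustering` (single cluster if all points coincide).
#' @export
peak_cluster <- function(peaks) {
  if (is.data.frame(peaks)) {
    rn <- if ("area" %in% names(peaks)) peaks$area else rownames(peaks)
    peaks <- as.matrix(peaks[, c("x", "y", "z")])
    rownames(peaks) <- rn
  }
  if (nrow(peaks) < 3) stop("peak_cluster: need at least 3 peaks")
  d <- as.matrix(stats::dist(peaks))
  med <- stats::median(d[upper.tri(d)])
  if (med == 0) {
    labels <- stats::setNames(rep(1L, nrow(peaks)), rownames(peaks))
    return(structure(list(labels = labels, n_clusters = 1L, modularity = 0),
                     class = "spectral_clustering"))
  }
  aff <- exp(-d^2 / (2 * med^2))
  diag(aff) <- 0
  spectral_clusters(aff)
}

#' Network-structure analysis of connectivity maps
#'
#' Composes the similarity / MDS / clustering / overlap / peak analyses:
#' hemisphere-averaged map similarity, its Euclidean dissimilarity, the 2D
#' classical MDS configuration, spectral modularity clusters, the Dice
#' matrix per hemisphere, and per-area bilateral peak coordinates.
#'
#' @param conn a `connectivity_maps` object.
#' @param p_threshold threshold for the Dice masks (default 0.05 on q).
#' @return object of class `network_structure`.
#' @export
network_structure <- function(conn, p_threshold = 0.05) {
  sim <- map_similarity(conn)
  dis <- similarity_to_dissimilarity(sim)
  mds <- classical_mds(dis, dims = 2)
  clus <- spectral_clusters(sim)
  hemis <- attr(conn, "hemispheres")
  dice <- lapply(hemis, function(h) {
    g <- conn[[h]]$group
    colnames(g$q) <- colnames(g$p) <- colnames(g$t) <- conn[[h]]$area_names
    dice_matrix(g, p_threshold = p_threshold)
  })
  names(dice) <- hemis
  peaks <- .bilateral_peaks(conn)
  structure(list(map_similarity = sim, dissimilarity = dis, mds_coords = mds,
                 clusters = clus, dice = dice, peaks = peaks),
            class = "network_structure")
}

.bilateral_peaks <- function(conn) {
  hemis <- attr(conn, "hemispheres")
  base_names <- sub("_[LR]$", "", conn[[hemis[1]]]$area_names)
  pk_h <- lapply(hemis, function(h) {
    g <- conn[[h]]$group$mean
    t(vapply(seq_len(ncol(g)), function(a) {
      peak_location(g[, a], conn[[h]]$voxel_coords)
    }, numeric(3)))
  })
  names(pk_h) <- hemis
  if (length(hemis) == 2) {
    out <- t(vapply(seq_along(base_names), function(a) {
      bilateral_average(pk_h[["L"]][a, ], pk_h[["R"]][a, ])
    }, numeric(3)))
  } else {
    out <- pk_h[[1]]
  }
  data.frame(area = base_names, x = out[, 1], y = out[, 2], z = out[, 3])
}

#' @export
print.network_structure <- function(x, ...) {
  cat("network_structure:\n")
  cat(sprintf("  %d areas, %d clusters (Q = %.3f)\n",
              nrow(x$map_similarity), x$clusters$n_clusters,
              x$clusters$modularity))
  invisible(x)
}

#' Scatter plot of the MDS configuration colored by cluster
#' @param x a `network_structure`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.network_structure <- function(x, ...) {
  cl <- x$clusters$labels
  graphics::plot(x$mds_coords, col = cl + 1, pch = 19,
                 xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  graphics::text(x$mds_coords, labels = rownames(x$mds_coords), pos = 3,
                 cex = 0.6)
  invisible(x)
}
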