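# Independent brute-force oracles used to validate the package's numerics.

# Textbook Pearson correlation from sums (no stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Benjamini-Hochberg step-up rejection set, straight from the definition:
# reject H_(1..k) where k = max { i : p_(i) <= i * q / m }.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# BH adjusted values from the definition q_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Normalized full-Procrustes SSE in 2D by brute-force search over the
# rotation angle (reflection included), scale optimized in closed form per
# angle. sse = 1 - trace^2 / (ssx * ssy) at the best angle.
oracle_procrustes_sse <- function(source, target) {
  x <- scale(as.matrix(source), scale = FALSE)
  y <- scale(as.matrix(target), scale = FALSE)
  ssx <- sum(x^2); ssy <- sum(y^2)
  trace_at <- function(theta, reflect) {
    r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (reflect) r <- r %*% diag(c(1, -1))
    sum(diag(crossprod(y, x %*% r)))
  }
  best <- -Inf
  for (reflect in c(FALSE, TRUE)) {
    th <- seq(0, 2 * pi, by = 1e-3)
    tr <- vapply(th, trace_at, numeric(1), reflect = reflect)
    t0 <- th[which.max(tr)]
    fine <- seq(t0 - 2e-3, t0 + 2e-3, by = 1e-6)
    trf <- vapply(fine, trace_at, numeric(1), reflect = reflect)
    best <- max(best, max(trf))
  }
  1 - max(0, best)^2 / (ssx * ssy)
}

# Torgerson double-centering MDS from the definition.
oracle_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% d^2 %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  k <- seq_len(dims)
  lam <- pmax(e$values[k], 0)
  e$vectors[, k, drop = FALSE] %*% diag(sqrt(lam), dims)
}

# Compare two configurations that are each unique up to per-column sign.
expect_equal_up_to_sign <- function(a, b, tol = 1e-6) {
  a <- unname(as.matrix(a)); b <- unname(as.matrix(b))
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    d <- min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
    expect_lt(d, tol)
  }
}
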