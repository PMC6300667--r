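#' @keywords internal
"_PACKAGE"

#' Evaluate code under a fixed RNG seed without disturbing the global stream
#'
#' All generators and permutation routines route their randomness through
#' this helper so that every output is a pure function of its arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' Stages of the pipeline (simulation, permutation tests, split-half
#' resampling, ...) draw from independent substreams derived
#' deterministically from one configured seed.
#'
#' @param seed master integer seed.
#' @param label character substream name.
#' @return integer seed below 2^31.
#' @export
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563L) + 1L
}

#' Fisher r-to-z transform
#' @param r correlation(s) in (-1, 1).
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(r)
}

#' Inverse Fisher transform
#' @param z Fisher z value(s).
#' @return tanh(z).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Two-sample z test for the difference of two independent correlations
#'
#' Compares two Pearson correlations via the Fisher transform:
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-tailed
#' normal p value. Note the test assumes independent samples; when the two
#' correlations share observations (e.g. area pairs drawn from one area set)
#' the p value is approximate and a caveat is attached to the result.
#'
#' @param r1,r2 correlations, |r| < 1.
#' @param n1,n2 sample sizes (> 3).
#' @param dependent logical; set TRUE to flag that the samples overlap.
#' @return list with `z`, `p`, and `caveat`.
#' @export
fisher_z_difference <- function(r1, n1, r2, n2, dependent = FALSE) {
  stopifnot(n1 > 3, n2 > 3)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("fisher_z_difference: |r| must be < 1")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(
    z = z, p = p,
    caveat = if (dependent) {
      "correlations computed on overlapping samples; independent-samples test is approximate"
    } else {
      NA_character_
    }
  )
}

#' Pearson correlation between two vectors, NA-safe for degenerate input
#' @keywords internal
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Simple message logger used by pipeline stages
#' @keywords internal
pv_log <- function(..., verbose = getOption("pulvicor.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[pulvicor] ", ...)
  invisible(NULL)
}
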