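#' @keywords internal
"_PACKAGE"

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards.  All stochastic functions in the package route their
## randomness through this helper so that a single integer seed makes every
## generator reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic sub-seed derivation (stream splitting): sub-streams for
## trials/channels/blocks are derived from the master seed by mixing in an
## index, kept inside 32-bit integer range.
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629) + 1L
}

## Moving 2-D box sum with border truncation: out[i,j] = sum of m over the
## (2h+1)x(2h+1) window centred at (i,j), clipped to the matrix.  Computed
## with a summed-area table so decision-matrix smoothing is O(cells).
box_sum2d <- function(m, half) {
  n1 <- nrow(m); n2 <- ncol(m)
  cs <- matrix(apply(m, 2, cumsum), n1, n2)
  cs <- t(matrix(apply(cs, 1, cumsum), n2, n1))
  sat <- matrix(0, n1 + 1, n2 + 1)
  sat[2:(n1 + 1), 2:(n2 + 1)] <- cs
  i <- seq_len(n1); j <- seq_len(n2)
  lo1 <- pmax(i - half, 1); hi1 <- pmin(i + half, n1)
  lo2 <- pmax(j - half, 1); hi2 <- pmin(j + half, n2)
  out <- sat[hi1 + 1, hi2 + 1, drop = FALSE] -
    sat[lo1, hi2 + 1, drop = FALSE] -
    sat[hi1 + 1, lo2, drop = FALSE] +
    sat[lo1, lo2, drop = FALSE]
  out
}

## Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))
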