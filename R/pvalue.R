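#' Exact null distribution of window scores by dynamic programming
#'
#' Each column's four scores are rounded to a grid of `grid` bits per bin
#' and the distribution of the total score of one random i.i.d. background
#' window is built by positionwise convolution. The result supports exact
#' match p-values P(score >= s) for any s; for short motifs this agrees with
#' exhaustive enumeration of all 4^width windows (the test oracle).
#'
#' @param lom A [LogOddsMatrix-class].
#' @param bg A [Background-class]; defaults to the one the matrix was built
#'   against.
#' @param grid Bits per bin (default 0.001).
#' @return A [ScoreDistribution-class].
#' @export
scoreDistribution <- function(lom, bg = lom@background, grid = 0.001) {
  stopifnot(is(lom, "LogOddsMatrix"), is(bg, "Background"), grid > 0)
  bins <- round(lom@scores / grid)
  storage.mode(bins) <- "integer"
  w <- ncol(bins)
  kmin <- sum(apply(bins, 2, min))
  kmax <- sum(apply(bins, 2, max))
  n <- kmax - kmin + 1L
  # pmf over binned total score, offset so index 1 == kmin
  pmf <- numeric(n)
  colmins <- apply(bins, 2, min)
  # running range: after column j, totals lie in [sum(min_1..j), sum(max_1..j)]
  pmf[1L] <- 1
  cur_lo <- 0L  # offset of pmf[1] relative to the running minimum
  cur_len <- 1L
  p <- bg@probs
  run_min <- 0L
  for (j in seq_len(w)) {
    new <- numeric(n)
    cb <- bins[, j] - colmins[j]
    for (b in 1:4) {
      sh <- cb[b]
      if (p[b] > 0 && cur_len > 0)
        new[(1L + sh):(cur_len + sh)] <-
          new[(1L + sh):(cur_len + sh)] + p[b] * pmf[1:cur_len]
    }
    pmf <- new
    cur_len <- cur_len + max(cb)
    run_min <- run_min + colmins[j]
  }
  tail <- rev(cumsum(rev(pmf[1:cur_len])))
  # guard against fp drift: tail must start at exactly 1 and be monotone
  tail <- pmin(pmax(tail, 0), 1)
  tail[1] <- 1
  tail <- cummin(tail)
  new("ScoreDistribution", motifId = lom@motifId, grid = grid,
      bins = bins, kmin = as.integer(kmin), tail = tail,
      realRange = c(lom@minScore, lom@maxScore))
}

#' Exact match p-value for a score
#'
#' P(score >= s) for a single random background window. Scores below the
#' attainable minimum clamp to 1; scores above the maximum clamp to 0.
#'
#' @param dist A [ScoreDistribution-class].
#' @param s Score(s) in bits (vectorized).
#' @return Probability vector of the same length as `s`.
#' @export
scorePValue <- function(dist, s) {
  k <- as.integer(round(s / dist@grid))
  n <- length(dist@tail)
  kmax <- dist@kmin + n - 1L
  # a raw score within half a bin of the attainable range maps onto the
  # support (sum-of-rounds and round-of-sum can differ by a bin)
  half <- dist@grid / 2
  k[k > kmax & s <= dist@realRange[2] + half] <- kmax
  k[k < dist@kmin & s >= dist@realRange[1] - half] <- dist@kmin
  .binnedPValue(dist, k)
}

# p-value from an already-binned total score (used by the scanner so that
# scan p-values are exactly the DP tail of the discretized matrix)
.binnedPValue <- function(dist, k) {
  n <- length(dist@tail)
  idx <- k - dist@kmin + 1L
  out <- numeric(length(k))
  out[idx < 1L] <- 1
  out[idx > n] <- 0
  ok <- idx >= 1L & idx <= n
  out[ok] <- dist@tail[idx[ok]]
  out
}

setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf(
    "ScoreDistribution for %s: grid %g bits, support [%.4f, %.4f] bits\n",
    object@motifId, object@grid, object@kmin * object@grid,
    (object@kmin + length(object@tail) - 1L) * object@grid))
})
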