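#' Convert a count matrix to a log-odds scoring matrix
#'
#' FIMO-style conversion: the pseudocount is distributed across bases in
#' proportion to the background, so
#' `score(b, j) = log2( (count(b,j) + pseudocount * bg(b)) /
#' (total(j) + pseudocount) / bg(b) )` in bits. A column whose frequencies
#' equal the background scores 0 for every base.
#'
#' @param pwm A [MotifMatrix-class].
#' @param bg A [Background-class].
#' @param pseudocount Total pseudocount per column (default 0.1). Must be
#'   positive if any count is zero, otherwise the log-odds would be infinite.
#' @return A [LogOddsMatrix-class] carrying the score range and per-column
#'   information content.
#' @export
pwmLogOdds <- function(pwm, bg = background(), pseudocount = 0.1) {
  stopifnot(is(pwm, "MotifMatrix"), is(bg, "Background"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  counts <- pwm@counts
  if (pseudocount == 0 && any(counts == 0))
    stop(sprintf(
      "motif '%s' has zero counts; a positive pseudocount is required",
      pwm@motifId))
  p <- bg@probs
  totals <- colSums(counts)
  freq <- sweep(counts + pseudocount * p,
                2, totals + pseudocount, "/")
  scores <- log2(freq / p)
  dimnames(scores) <- dimnames(counts)
  # information content from the raw column frequencies (0 log 0 := 0)
  prob <- sweep(counts, 2, totals, "/")
  term <- prob * log2(prob / p)
  term[prob == 0] <- 0
  ic <- colSums(term)
  new("LogOddsMatrix", motifId = pwm@motifId, scores = scores,
      minScore = sum(apply(scores, 2, min)),
      maxScore = sum(apply(scores, 2, max)),
      ic = ic, background = bg)
}

#' Build a log-odds matrix directly from base probabilities
#'
#' Convenience for toy matrices specified as per-column probabilities
#' rather than counts; no pseudocount is applied.
#'
#' @param probs 4 x width matrix of per-column base probabilities
#'   (rows A, C, G, T).
#' @param bg A [Background-class].
#' @param motifId Identifier for the resulting matrix.
#' @return A [LogOddsMatrix-class].
#' @export
probsToLogOdds <- function(probs, bg = background(), motifId = "toy") {
  stopifnot(is.matrix(probs), nrow(probs) == 4)
  rownames(probs) <- DNA_BASES
  scores <- log2(probs / bg@probs)
  term <- probs * log2(probs / bg@probs)
  term[probs == 0] <- 0
  new("LogOddsMatrix", motifId = motifId, scores = scores,
      minScore = sum(apply(scores, 2, min)),
      maxScore = sum(apply(scores, 2, max)),
      ic = colSums(term), background = bg)
}

#' @describeIn pwmLogOdds Score matrix accessor (bits).
#' @param x A `LogOddsMatrix`.
#' @export
lomScores <- function(x) x@scores

#' @describeIn pwmLogOdds Attainable score range, `c(min, max)`, in bits.
#' @export
scoreRange <- function(x) c(min = x@minScore, max = x@maxScore)

#' @describeIn pwmLogOdds Per-column information content in bits.
#' @export
informationContent <- function(x) {
  if (is(x, "LogOddsMatrix")) return(x@ic)
  stopifnot(is(x, "MotifMatrix"))
  prob <- sweep(x@counts, 2, colSums(x@counts), "/")
  term <- prob * log2(prob / 0.25)
  term[prob == 0] <- 0
  colSums(term)
}

#' Consensus sequence of a motif (column maxima)
#'
#' Ties are broken in A, C, G, T order so the result is deterministic.
#'
#' @param x A `MotifMatrix` or `LogOddsMatrix`.
#' @return Character scalar.
#' @export
consensusSequence <- function(x) {
  m <- if (is(x, "MotifMatrix")) x@counts else x@scores
  paste(DNA_BASES[apply(m, 2, which.max)], collapse = "")
}

#' Score one window of sequence against a log-odds matrix
#'
#' @param lom A [LogOddsMatrix-class].
#' @param window Character scalar of length `motifWidth(lom)`, bases ACGT.
#' @return Score in bits (sum of per-position log2 odds).
#' @export
scoreWindow <- function(lom, window) {
  w <- ncol(lom@scores)
  bases <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(bases) != w)
    stop(sprintf("window length %d != motif width %d", length(bases), w))
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx))
    stop("window contains non-ACGT characters")
  sum(lom@scores[cbind(idx, seq_len(w))])
}

.encodeSequence <- function(seq) {
  s <- toupper(as.character(seq))
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

.transitionMap <- c(A = "G", C = "T", G = "A", T = "C")

#' Transition partner of a base
#'
#' A<->G (purines), C<->T (pyrimidines); involutive. This is the
#' site-disruption rule: mutating to the other purine/pyrimidine breaks
#' motif matches while preserving purine/pyrimidine identity.
#'
#' @param base Single character in A, C, G, T (case-insensitive).
#' @return The transition partner, upper case.
#' @examples
#' transitionBase("A")  # "G"
#' transitionBase("C")  # "T"
#' @export
transitionBase <- function(base) {
  b <- toupper(base)
  out <- .transitionMap[b]
  if (anyNA(out)) stop(sprintf("no transition partner for '%s'", base))
  unname(out)
}
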