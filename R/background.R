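#' Construct a zero-order background model
#'
#' @param probA,probC,probG,probT Base probabilities; must be positive and
#'   sum to 1.
#' @return A [Background-class] object.
#' @examples
#' background()                # uniform
#' background(0.3, 0.2, 0.2, 0.3)
#' @export
background <- function(probA = 0.25, probC = 0.25, probG = 0.25, probT = 0.25) {
  new("Background", probs = c(A = probA, C = probC, G = probG, T = probT))
}

#' Estimate a background from a sequence
#'
#' Zero-order base frequencies of the scanned sequence itself, with a small
#' pseudocount so no probability is zero. Non-ACGT characters are ignored.
#'
#' @param seq Character scalar or [Biostrings::DNAString] object.
#' @param pseudocount Added to each base count before normalizing.
#' @return A [Background-class] object.
#' @export
backgroundFromSequence <- function(seq, pseudocount = 1) {
  s <- toupper(as.character(seq))
  n <- vapply(DNA_BASES, function(b)
    sum(strsplit(s, "", fixed = TRUE)[[1]] == b), numeric(1))
  p <- (n + pseudocount) / sum(n + pseudocount)
  background(p[1], p[2], p[3], p[4])
}

#' @describeIn background Accessor for the probability vector.
#' @param x A `Background` object.
#' @export
bgProbs <- function(x) x@probs

setMethod("show", "Background", function(object) {
  cat("Background (i.i.d.):",
      paste(sprintf("%s=%.4g", DNA_BASES, object@probs), collapse = " "), "\n")
})
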