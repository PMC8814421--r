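#' Genomic interval of the proximal brachyury enhancer
#'
#' The 377-bp proximal enhancer fragment, an ATAC-seq peak over the
#' upstream region and first exon of the brachyury locus on scaffold
#' KhS1404 (positions 5981-6357, 1-based inclusive).
#'
#' @return A [GenomicRanges::GRanges] of width 377.
#' @examples
#' GenomicRanges::width(braEnhancerInterval())  # 377
#' @export
braEnhancerInterval <- function() {
  GenomicRanges::GRanges("KhS1404", IRanges::IRanges(5981, 6357))
}

#' Stylized example motifs
#'
#' Synthetic count matrices shaped like the ETS-family and RBPJ binding
#' preferences relevant to notochord induction: both carry the shared GGAA
#' core (near-invariant columns) flanked by more variable positions. They
#' are illustrative stand-ins built in code — not JASPAR profiles — for
#' examples, vignettes and simulations.
#'
#' @return A [MotifMatrix-class].
#' @export
etsExampleMotif <- function() {
  # consensus ACCGGAAGT; GGAA core at columns 4-7
  counts <- matrix(c(
    # A   C   G   T  (per column, written column-wise)
    60, 20, 10, 10,
    10, 70, 10, 10,
    10, 75,  5, 10,
     1,  1, 97,  1,
     1,  1, 97,  1,
    97,  1,  1,  1,
    90,  2,  4,  4,
    10, 15, 65, 10,
    10, 15, 10, 65), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  new("MotifMatrix", motifId = "ETS_demo", factorName = "Ets-family",
      counts = counts)
}

#' @rdname etsExampleMotif
#' @export
rbpjExampleMotif <- function() {
  # consensus CGTGGGAA; GGAA core at columns 5-8
  counts <- matrix(c(
    10, 60, 15, 15,
    10, 10, 65, 15,
    10, 10, 10, 70,
     2,  2, 94,  2,
     1,  1, 97,  1,
     1,  1, 97,  1,
    97,  1,  1,  1,
    92,  3,  3,  2), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  new("MotifMatrix", motifId = "RBPJ_demo", factorName = "RBPJ/Su(H)",
      counts = counts)
}
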