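#' @export
setMethod("show", "LogOddsMatrix", function(object) {
  cat(sprintf("LogOddsMatrix %s: width %d, score range [%.3f, %.3f] bits\n",
              object@motifId, ncol(object@scores), object@minScore,
              object@maxScore))
})

#' @export
setMethod("show", "ScanConfig", function(object) {
  cat(sprintf(
    "ScanConfig: p <= %g, pseudocount %g, %s, grid %g bits\n",
    object@pThreshold, object@pseudocount,
    if (object@bothStrands) "both strands" else "forward strand",
    object@gridResolution))
})

#' @export
setMethod("show", "MutationPlan", function(object) {
  s <- object@substitutions
  if (nrow(s) == 0) {
    cat("MutationPlan: no substitutions\n")
  } else {
    cat(sprintf("MutationPlan: %d transition substitution(s): %s\n",
                nrow(s),
                paste(sprintf("%s%d%s", s$ref, s$position, s$alt),
                      collapse = ", ")))
  }
})

#' @export
setMethod("show", "InfeasibilityRecord", function(object) {
  cat("InfeasibilityRecord:", object@message, "\n")
  if (nrow(object@conflicts) > 0) {
    cat("conflicting protected hits per candidate:\n")
    print(object@conflicts)
  }
})

#' @export
setMethod("show", "VerificationReport", function(object) {
  cat(sprintf(
    "VerificationReport: %s (lost targets %d, surviving %d, lost protected %d, new %d)\n",
    if (object@passed) "PASSED" else "FAILED",
    nrow(object@lostTargetHits), nrow(object@survivingTargetHits),
    nrow(object@lostProtectedHits), nrow(object@newHits)))
})

#' @export
setMethod("show", "EnhancerVariant", function(object) {
  cat(sprintf("EnhancerVariant '%s': %d bp, %d substitution(s), %s\n",
              object@name, nchar(object@sequence),
              nrow(object@plan@substitutions),
              if (object@report@passed) "verified" else "NOT verified"))
})

#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d channel(s) [%s], Z=%d, %dx%d\n",
              d[1], paste(dimnames(object@voxels)[[1]], collapse = ", "),
              d[2], d[3], d[4]))
})

#' Accessors for designed variants and reports
#'
#' @param x An [EnhancerVariant-class] or [VerificationReport-class].
#' @name variant-accessors
NULL

#' @rdname variant-accessors
#' @export
variantSequence <- function(x) x@sequence

#' @rdname variant-accessors
#' @export
variantPlan <- function(x) x@plan

#' @rdname variant-accessors
#' @export
variantReport <- function(x) x@report

#' @rdname variant-accessors
#' @export
verificationPassed <- function(x) {
  if (is(x, "EnhancerVariant")) x@report@passed else x@passed
}

#' @rdname variant-accessors
#' @export
planSubstitutions <- function(x) {
  if (is(x, "EnhancerVariant")) x@plan@substitutions else x@substitutions
}
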