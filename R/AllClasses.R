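#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Zero-order background base composition
#'
#' An i.i.d. (zero-order) model of background base frequencies used for
#' log-odds scoring and exact match p-values. The default is uniform
#' (0.25 per base), which is the reproducible choice when the true genomic
#' background is unknown; [backgroundFromSequence()] estimates one from the
#' scanned sequence instead.
#'
#' @slot probs Named numeric vector of probabilities for A, C, G, T.
#' @export
setClass("Background", representation(probs = "numeric"))

setValidity("Background", function(object) {
  p <- object@probs
  if (!identical(names(p), DNA_BASES))
    return("probs must be named A, C, G, T in that order")
  if (any(p <= 0) || any(p >= 1))
    return("each background probability must lie in (0, 1)")
  if (abs(sum(p) - 1) > 1e-9)
    return("background probabilities must sum to 1 (tolerance 1e-9)")
  TRUE
})

#' Position count matrix for a transcription factor binding motif
#'
#' Per-position base counts in the JASPAR style: a 4 x width matrix with rows
#' A, C, G, T. Counts need not be integers (JASPAR stores reals for some
#' profiles) but must be non-negative with a positive total per column.
#'
#' @slot motifId Motif identifier (e.g. a JASPAR accession).
#' @slot factorName Transcription factor name, possibly empty.
#' @slot counts 4 x width numeric matrix, rownames A, C, G, T.
#' @export
setClass("MotifMatrix", representation(
  motifId = "character", factorName = "character", counts = "matrix"))

setValidity("MotifMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m) || !identical(rownames(m), DNA_BASES))
    return("counts must be a numeric matrix with rows A, C, G, T")
  if (ncol(m) < 1) return("motif width must be >= 1")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(colSums(m) <= 0)) return("every column must have a positive total count")
  TRUE
})

#' Log-odds scoring matrix derived from a count matrix
#'
#' Per-position log2 odds (bits) of each base under the motif model relative
#' to a background, plus the attainable score range and per-column
#' information content (used to rank positions by importance when designing
#' knockouts).
#'
#' @slot motifId Motif identifier.
#' @slot scores 4 x width numeric matrix of log2 odds in bits.
#' @slot minScore Sum of column minima (worst attainable window score).
#' @slot maxScore Sum of column maxima (consensus score).
#' @slot ic Per-column information content in bits (relative entropy to the
#'   background).
#' @slot background The [Background-class] the scores were computed against.
#' @export
setClass("LogOddsMatrix", representation(
  motifId = "character", scores = "matrix", minScore = "numeric",
  maxScore = "numeric", ic = "numeric", background = "Background"))

setValidity("LogOddsMatrix", function(object) {
  s <- object@scores
  if (!identical(rownames(s), DNA_BASES))
    return("scores must have rows A, C, G, T")
  if (abs(object@minScore - sum(apply(s, 2, min))) > 1e-8)
    return("minScore must equal the sum of column minima")
  if (abs(object@maxScore - sum(apply(s, 2, max))) > 1e-8)
    return("maxScore must equal the sum of column maxima")
  if (length(object@ic) != ncol(s))
    return("ic must hold one value per column")
  TRUE
})

#' Exact null distribution of window scores
#'
#' The distribution of the log-odds score of a single random background
#' window, computed by positionwise convolution of the per-column score
#' distributions after rounding scores to a fixed grid. `tail[k]` is
#' P(score >= kmin + k - 1 grid units).
#'
#' @slot motifId Motif identifier.
#' @slot grid Bits per bin (discretization resolution).
#' @slot bins 4 x width integer matrix of column scores in grid units.
#' @slot kmin Smallest attainable binned total score.
#' @slot tail Numeric vector of upper-tail probabilities, non-increasing,
#'   `tail[1] == 1`.
#' @slot realRange Attainable un-discretized score range `c(min, max)`,
#'   used to clamp boundary queries.
#' @export
setClass("ScoreDistribution", representation(
  motifId = "character", grid = "numeric", bins = "matrix",
  kmin = "integer", tail = "numeric", realRange = "numeric"))

setValidity("ScoreDistribution", function(object) {
  tl <- object@tail
  if (object@grid <= 0) return("grid must be positive")
  if (length(tl) < 1 || abs(tl[1] - 1) > 1e-12)
    return("tail must start at 1 (every window scores at least the minimum)")
  if (any(diff(tl) > 1e-12)) return("tail probabilities must be non-increasing")
  TRUE
})

#' Scanning configuration
#'
#' @slot pThreshold Report a window as a hit iff its match p-value is
#'   `<= pThreshold`.
#' @slot pseudocount Total pseudocount added to each column, distributed by
#'   background probability (FIMO-style).
#' @slot bothStrands Scan the reverse complement as well.
#' @slot gridResolution Bits per bin for the exact p-value computation.
#' @export
setClass("ScanConfig", representation(
  pThreshold = "numeric", pseudocount = "numeric", bothStrands = "logical",
  gridResolution = "numeric"))

setValidity("ScanConfig", function(object) {
  if (object@pThreshold <= 0 || object@pThreshold > 1)
    return("pThreshold must lie in (0, 1]")
  if (object@pseudocount < 0) return("pseudocount must be >= 0")
  if (object@gridResolution <= 0) return("gridResolution must be positive")
  TRUE
})

#' A set of transition substitutions knocking out target sites
#'
#' Only transition substitutions (A<->G, C<->T) are ever proposed, so that
#' purine/pyrimidine identity is preserved and both palindromic and
#' non-palindromic motifs are disrupted without altering sequence length.
#'
#' @slot substitutions data.frame with columns `position` (1-based), `ref`,
#'   `alt`; positions unique, every alt the transition partner of its ref.
#' @slot targetHitIds Identifiers of the hits this plan is meant to destroy.
#' @export
setClass("MutationPlan", representation(
  substitutions = "data.frame", targetHitIds = "character"))

setValidity("MutationPlan", function(object) {
  s <- object@substitutions
  need <- c("position", "ref", "alt")
  if (!all(need %in% names(s)))
    return("substitutions needs columns position, ref, alt")
  if (anyDuplicated(s$position)) return("substitution positions must be unique")
  if (nrow(s) > 0 && !all(s$alt == vapply(s$ref, transitionBase, character(1))))
    return("every alt must be the transition partner of its ref")
  TRUE
})

#' Constraints for knockout design
#'
#' @slot targetMotifIds Motifs whose sites must be destroyed.
#' @slot watchMotifIds All motifs of interest; the variant must not gain or
#'   lose sites for any of them except as allowed.
#' @slot protectedHits Hit table (as returned by [scanSequence()]) of sites
#'   that must survive at identical coordinates and strand.
#' @slot allowedCollateral Hit ids of protected sites that are permitted to
#'   be lost (e.g. RBPJ sites overlapping low-scoring ETS sites).
#' @slot kMax Maximum substitutions per target site (default 4).
#' @slot pThreshold Match p-value threshold defining a site.
#' @export
setClass("DesignConstraints", representation(
  targetMotifIds = "character", watchMotifIds = "character",
  protectedHits = "data.frame", allowedCollateral = "character",
  kMax = "integer", pThreshold = "numeric"))

setValidity("DesignConstraints", function(object) {
  if (object@kMax < 1) return("kMax must be >= 1")
  if (object@pThreshold <= 0 || object@pThreshold > 1)
    return("pThreshold must lie in (0, 1]")
  TRUE
})

#' Record of an infeasible knockout design
#'
#' Returned instead of a [MutationPlan-class] when no combination of up to
#' `kMax` transitions destroys the target site without violating the
#' constraints. `conflicts` lists, for the best candidate plans (those that
#' did destroy the target), which protected hits each would have destroyed.
#'
#' @slot hitId The target hit that could not be knocked out.
#' @slot conflicts data.frame with columns `candidate` (substitution summary)
#'   and `destroys` (protected hit id).
#' @slot message Human-readable explanation.
#' @export
setClass("InfeasibilityRecord", representation(
  hitId = "character", conflicts = "data.frame", message = "character"))

#' Rescan verification of an enhancer variant
#'
#' @slot lostTargetHits Wildtype target-motif hits absent from the variant.
#' @slot survivingTargetHits Wildtype target-motif hits still present.
#' @slot lostProtectedHits Protected hits absent from the variant.
#' @slot newHits Variant hits (any watch motif) absent from the wildtype.
#' @slot passed TRUE iff no surviving target hits, no new hits, and every
#'   lost protected hit was explicitly allowed as collateral.
#' @export
setClass("VerificationReport", representation(
  lostTargetHits = "data.frame", survivingTargetHits = "data.frame",
  lostProtectedHits = "data.frame", newHits = "data.frame",
  passed = "logical"))

#' A designed enhancer variant
#'
#' @slot name Construct name.
#' @slot sequence Variant sequence (same length as the wildtype; differs from
#'   it exactly at the plan positions).
#' @slot plan The [MutationPlan-class] that produced it.
#' @slot report The [VerificationReport-class] from the final rescan.
#' @export
setClass("EnhancerVariant", representation(
  name = "character", sequence = "character", plan = "MutationPlan",
  report = "VerificationReport"))

#' Multi-channel image stack
#'
#' Voxel intensities as a channels x Z x Y x X array plus a mapping from
#' channel roles (reporter, control, counterstain) to channel names.
#'
#' @slot voxels 4-d non-negative numeric array, dim = (channel, z, y, x),
#'   with channel dimnames.
#' @slot channelRoles Named character vector mapping roles to channel names.
#' @export
setClass("ImageStack", representation(
  voxels = "array", channelRoles = "character"))

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 4) return("voxels must be a 4-d array (C, Z, Y, X)")
  if (dim(v)[1] < 2) return("an ImageStack needs at least 2 channels")
  if (any(v < 0)) return("intensities must be non-negative")
  if (is.null(dimnames(v)[[1]])) return("channels must be named")
  if (!all(object@channelRoles %in% dimnames(v)[[1]]))
    return("channelRoles must name existing channels")
  TRUE
})

#' Region-of-interest polygons for one embryo
#'
#' Polygons are n x 2 matrices of (x, y) vertices in projected pixel
#' coordinates; pixel (row, col) has its center at (x = col, y = row).
#' Primary/secondary lineage polygons are optional (0-row matrices).
#'
#' @slot whole Polygon around the whole notochord.
#' @slot primary Polygon around the anterior 32 primary-lineage cells.
#' @slot secondary Polygon around the posterior 8 secondary-lineage cells.
#' @export
setClass("ROISet", representation(
  whole = "matrix", primary = "matrix", secondary = "matrix"))

setValidity("ROISet", function(object) {
  for (nm in c("whole", "primary", "secondary")) {
    p <- slot(object, nm)
    if (ncol(p) != 2) return(sprintf("%s polygon must have 2 columns (x, y)", nm))
    if (nm == "whole" && nrow(p) < 3) return("whole polygon needs >= 3 vertices")
  }
  TRUE
})

#' Single-cell analysis configuration
#'
#' @slot controlThreshold Intensity above which a cell counts as expressing
#'   the internal control (strict `>`; default 256, i.e. 8 in log2 units).
#' @slot reporterThreshold Intensity above which a cell counts as expressing
#'   the reporter (default the same 256).
#' @slot diskRadius Radius in pixels of the nuclear disk ROIs.
#' @slot logFloor Intensities are floored at this value before log2 so that
#'   zeros stay finite while log2(256) = 8 exactly (default 1).
#' @export
setClass("SingleCellConfig", representation(
  controlThreshold = "numeric", reporterThreshold = "numeric",
  diskRadius = "numeric", logFloor = "numeric"))

setValidity("SingleCellConfig", function(object) {
  if (object@controlThreshold <= 0) return("controlThreshold must be > 0")
  if (object@logFloor <= 0) return("logFloor must be > 0")
  TRUE
})

#' Configuration for simulating an enhancer sequence
#'
#' @slot length Sequence length in bp (default 377, the size of the proximal
#'   brachyury enhancer fragment).
#' @slot gcContent GC proportion of the i.i.d. background.
#' @slot plants data.frame with columns `motif_id`, `position` (1-based start),
#'   `strand`, `mode` ("consensus" or "sample").
#' @slot exclusionThreshold Background is rejection-resampled until no library
#'   motif hits at p <= this threshold outside planted intervals.
#' @slot seed Integer RNG seed.
#' @slot maxAttempts Resampling budget before giving up.
#' @export
setClass("SequenceSimConfig", representation(
  length = "integer", gcContent = "numeric", plants = "data.frame",
  exclusionThreshold = "numeric", seed = "integer", maxAttempts = "integer"))

setValidity("SequenceSimConfig", function(object) {
  if (object@length < 1) return("length must be >= 1")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    return("gcContent must lie in (0, 1)")
  TRUE
})

#' Configuration for simulating dual-reporter measurements
#'
#' The generative model: each embryo draws an electroporation efficiency
#' E ~ LogNormal(0, efficiencySigma^2) shared by both channels; each cell
#' takes up the (co-segregating) plasmid mix with probability `mosaicism`;
#' an expressing cell emits reporter `strength * reporterScale *
#' secondary_attenuation^[secondary] * E * eps` and control
#' `controlStrength * E * eps'`, with eps ~ LogNormal(0, cellSigma^2)
#' independently per cell and channel; non-expressing cells emit `baseline`.
#'
#' @slot constructs data.frame with columns `construct_id`, `strength`,
#'   `mosaicism`, `secondary_attenuation`.
#' @slot nEmbryos Embryos per construct per replicate.
#' @slot nReplicates Biological replicates (electroporation days).
#' @slot efficiencySigma sdlog of the per-embryo efficiency.
#' @slot cellSigma sdlog of the per-cell multiplicative noise.
#' @slot baseline Intensity emitted by non-expressing cells.
#' @slot cellsPrimary,cellsSecondary Cells per lineage (defaults 32 and 8).
#' @slot controlStrength Mean control intensity of an expressing cell at E=1.
#' @slot reporterScale Converts relative construct strength to intensity.
#' @slot correlatedUptake If TRUE (default) one uptake event drives both
#'   channels; if FALSE reporter and control mosaicism are independent.
#' @slot wildtypeId Which construct id is the wildtype anchor.
#' @slot seed Integer RNG seed.
#' @export
setClass("ExpressionSimConfig", representation(
  constructs = "data.frame", nEmbryos = "integer", nReplicates = "integer",
  efficiencySigma = "numeric", cellSigma = "numeric", baseline = "numeric",
  cellsPrimary = "integer", cellsSecondary = "integer",
  controlStrength = "numeric", reporterScale = "numeric",
  correlatedUptake = "logical", wildtypeId = "character", seed = "integer"))

setValidity("ExpressionSimConfig", function(object) {
  cs <- object@constructs
  need <- c("construct_id", "strength", "mosaicism", "secondary_attenuation")
  if (!all(need %in% names(cs)))
    return("constructs needs columns construct_id, strength, mosaicism, secondary_attenuation")
  if (any(cs$strength < 0)) return("strengths must be >= 0")
  if (any(cs$mosaicism < 0 | cs$mosaicism > 1))
    return("mosaicism must lie in [0, 1]")
  if (object@efficiencySigma < 0 || object@cellSigma < 0)
    return("noise sigmas must be >= 0")
  TRUE
})
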