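#' Rank motif columns by importance
#'
#' "Important motif nucleotides" are operationalized as the columns with the
#' highest information content (relative entropy to the background, which is
#' `2 + sum(p * log2 p)` bits under a uniform background). Ties are broken
#' by leftmost column, so the ranking is total and the designer
#' deterministic.
#'
#' @param x A [MotifMatrix-class] or [LogOddsMatrix-class].
#' @param bg Unused for a `LogOddsMatrix` (its IC already encodes the
#'   background it was built with).
#' @return Integer vector of column indices, most informative first.
#' @export
rankPositions <- function(x, bg = background()) {
  ic <- informationContent(x)
  order(-ic, seq_along(ic))
}

#' Construct a mutation plan
#'
#' @param positions 1-based positions to substitute.
#' @param ref Reference bases at those positions.
#' @param alt Alternate bases; must be the transition partners of `ref`.
#' @param targetHitIds Hit ids this plan targets.
#' @return A [MutationPlan-class].
#' @export
mutationPlan <- function(positions = integer(), ref = character(),
                         alt = character(), targetHitIds = character()) {
  new("MutationPlan",
      substitutions = data.frame(position = as.integer(positions),
                                 ref = ref, alt = alt,
                                 stringsAsFactors = FALSE),
      targetHitIds = targetHitIds)
}

#' Construct design constraints
#'
#' @param targetMotifIds Motifs whose sites must be destroyed.
#' @param watchMotifIds All motifs of interest (defaults to the targets).
#' @param protectedHits Hit table of sites that must survive unchanged in
#'   coordinates and strand (p-value may change but must stay at or below
#'   `pThreshold`).
#' @param allowedCollateral Hit ids of protected sites allowed to be lost.
#' @param kMax Maximum substitutions per target site (default 4; sites are
#'   typically disrupted by mutating two to four nucleotides).
#' @param pThreshold Match p-value threshold defining a site (default 1e-3).
#' @return A [DesignConstraints-class].
#' @export
designConstraints <- function(targetMotifIds,
                              watchMotifIds = targetMotifIds,
                              protectedHits = .emptyHits(),
                              allowedCollateral = character(),
                              kMax = 4L, pThreshold = 1e-3) {
  new("DesignConstraints", targetMotifIds = targetMotifIds,
      watchMotifIds = unique(c(watchMotifIds, targetMotifIds)),
      protectedHits = protectedHits, allowedCollateral = allowedCollateral,
      kMax = as.integer(kMax), pThreshold = pThreshold)
}

#' Apply a mutation plan to a sequence
#'
#' @param seq Character scalar.
#' @param plan A [MutationPlan-class]; every `ref` must match `seq` at its
#'   position, otherwise the plan belongs to a different sequence version
#'   and an error is raised.
#' @return The variant sequence (same length).
#' @export
applyPlan <- function(seq, plan) {
  s <- toupper(as.character(seq))
  sub <- plan@substitutions
  if (nrow(sub) == 0) return(s)
  if (any(sub$position < 1 | sub$position > nchar(s)))
    stop("substitution position outside the sequence")
  have <- substring(s, sub$position, sub$position)
  bad <- have != sub$ref
  if (any(bad))
    stop(sprintf("ref mismatch at position %s: plan says %s, sequence has %s",
                 paste(sub$position[bad], collapse = ","),
                 paste(sub$ref[bad], collapse = ","),
                 paste(have[bad], collapse = ",")))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars[sub$position] <- sub$alt
  paste(chars, collapse = "")
}

#' Invert a mutation plan
#'
#' Swaps ref and alt; applying a plan and then its inverse restores the
#' original sequence exactly (transitions are involutive).
#'
#' @param plan A [MutationPlan-class].
#' @return The inverted plan.
#' @export
invertPlan <- function(plan) {
  s <- plan@substitutions
  mutationPlan(s$position, s$alt, s$ref, plan@targetHitIds)
}

.libDists <- function(library, bg, cfg) {
  stats::setNames(lapply(library, scoreDistribution, bg = bg,
                         grid = cfg@gridResolution), names(library))
}

.maxWidth <- function(library) max(vapply(library, motifWidth, numeric(1)))

# scan a local region of the sequence, returning hits in full-sequence
# coordinates
.scanRegion <- function(seq, from, to, library, bg, cfg, dists) {
  L <- nchar(seq)
  from <- max(1L, from); to <- min(L, to)
  sub <- substring(seq, from, to)
  hits <- scanLibrary(sub, library, bg, cfg, seqId = "region", dists = dists)
  hits$start <- hits$start + from - 1L
  hits$end <- hits$end + from - 1L
  hits
}

#' Design a knockout of a single motif hit
#'
#' Iterative-deepening search over transition substitutions inside the hit:
#' for k = 1..kMax, all k-subsets of hit positions are tried, ordered by
#' summed column information content (then leftmost position), and the first
#' plan that (i) leaves no window overlapping the original hit with target
#' p-value at or below the threshold on either strand, (ii) preserves every
#' protected hit touched by the edit (identical coordinates and strand,
#' p-value still at or below threshold) unless listed as allowed collateral,
#' and (iii) creates no new watch-motif hit near the edit, is returned.
#' If no plan passes, an [InfeasibilityRecord-class] lists which protected
#' hits each target-destroying candidate would have lost.
#'
#' @param seq Sequence currently being edited.
#' @param hit One-row hit data.frame for the site to destroy (must still be
#'   present on `seq`).
#' @param targetLom Log-odds matrix of the target motif.
#' @param constraints A [DesignConstraints-class].
#' @param bg Background model.
#' @param cfg A [ScanConfig-class]; its `pThreshold` should equal
#'   `constraints@pThreshold`.
#' @param library Named list of log-odds matrices for all watch motifs
#'   (used for protection and new-site checks).
#' @param dists Optional precomputed score distributions for `library`.
#' @param exclude Character vector of position-set keys
#'   (`paste(sort(positions), collapse=",")`) not to consider; used by
#'   [designConstruct()] to resume the search on later cycles.
#' @return A [MutationPlan-class] or an [InfeasibilityRecord-class].
#' @export
designSiteKnockout <- function(seq, hit, targetLom, constraints, bg, cfg,
                               library, dists = NULL,
                               exclude = character()) {
  stopifnot(nrow(hit) == 1)
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (is.null(dists)) dists <- .libDists(library, bg, cfg)
  w <- ncol(targetLom@scores)
  wmax <- .maxWidth(library)
  tid <- hit$motif_id

  # confirm the hit is live on this sequence
  live <- .scanRegion(seq, hit$start - 1L, hit$end + 1L,
                      library[tid], bg, cfg, dists[tid])
  if (!any(live$start == hit$start & live$end == hit$end &
           live$strand == hit$strand))
    stop(sprintf("hit %s:%d-%d(%s) is not present on the given sequence",
                 tid, hit$start, hit$end, hit$strand))

  positions <- hit$start:hit$end
  cols <- if (hit$strand == "+") positions - hit$start + 1L
          else hit$end - positions + 1L
  ic <- targetLom@ic[cols]

  protected <- constraints@protectedHits
  protKeys <- .hitIds(protected)
  baselineRegion <- .scanRegion(seq, hit$start - (wmax - 1L),
                                hit$end + (wmax - 1L),
                                library, bg, cfg, dists)
  baseKeys <- .hitIds(baselineRegion)

  conflicts <- data.frame(candidate = character(), destroys = character(),
                          stringsAsFactors = FALSE)

  for (k in seq_len(min(constraints@kMax, length(positions)))) {
    combos <- utils::combn(seq_along(positions), k, simplify = FALSE)
    sumIC <- vapply(combos, function(ix) sum(ic[ix]), numeric(1))
    # order: summed IC descending, then leftmost genomic positions
    keyvec <- vapply(combos, function(ix)
      paste(sprintf("%06d", sort(positions[ix])), collapse = ","),
      character(1))
    ord <- order(-sumIC, keyvec)
    for (ci in ord) {
      pos <- sort(positions[combos[[ci]]])
      posKey <- paste(pos, collapse = ",")
      if (posKey %in% exclude) next
      ref <- substring(seq, pos, pos)
      plan <- mutationPlan(pos, ref, vapply(ref, transitionBase,
                                            character(1)),
                           .hitIds(hit))
      variant <- applyPlan(seq, plan)

      # (i) target destroyed: no window overlapping the original interval
      # retains target p <= threshold on either strand
      tHits <- .scanRegion(variant, hit$start - (w - 1L), hit$end + (w - 1L),
                           library[tid], bg, cfg, dists[tid])
      tHits <- tHits[tHits$end >= hit$start & tHits$start <= hit$end, ,
                     drop = FALSE]
      if (nrow(tHits) > 0) next

      # (ii) protected hits touched by the edit must survive in place
      destroyed <- character()
      if (nrow(protected) > 0) {
        touched <- which(protected$end >= min(pos) - (wmax - 1L) &
                         protected$start <= max(pos) + (wmax - 1L))
        for (pi in touched) {
          ph <- protected[pi, ]
          win <- substring(variant, ph$start, ph$end)
          if (ph$strand == "-")
            win <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(win)))
          pd <- dists[[ph$motif_id]]
          if (is.null(pd))
            stop(sprintf("protected hit motif '%s' missing from library",
                         ph$motif_id))
          pv <- tryCatch(
            scorePValue(pd, scoreWindow(library[[ph$motif_id]], win)),
            error = function(e) 1)
          if (pv > constraints@pThreshold)
            destroyed <- c(destroyed, protKeys[pi])
        }
        destroyed <- setdiff(destroyed, constraints@allowedCollateral)
        if (length(destroyed) > 0) {
          conflicts <- rbind(conflicts, data.frame(
            candidate = posKey, destroys = destroyed,
            stringsAsFactors = FALSE))
          next
        }
      }

      # (iii) no new watch-motif hits near the edit
      after <- .scanRegion(variant, hit$start - (wmax - 1L),
                           hit$end + (wmax - 1L), library, bg, cfg, dists)
      newKeys <- setdiff(.hitIds(after), baseKeys)
      if (length(newKeys) > 0) next

      return(plan)
    }
  }

  new("InfeasibilityRecord", hitId = .hitIds(hit), conflicts = conflicts,
      message = sprintf(
        "no combination of up to %d transitions destroys %s:%d-%d(%s) within the constraints",
        constraints@kMax, tid, hit$start, hit$end, hit$strand))
}

#' Verify an enhancer variant by full rescan
#'
#' Rescans wildtype and variant with every watch matrix and classifies hits
#' by identity of (motif, start, end, strand): wildtype target-motif hits
#' absent from the variant are `lost`, those still present `surviving`;
#' variant hits absent from the wildtype are `new`; protected hits absent
#' from the variant are `lostProtected`. The report passes iff no target hit
#' survives, no new hit appears, and every lost protected hit was explicitly
#' allowed as collateral.
#'
#' @param wildtype,variant Same-length sequences.
#' @param library Named list of log-odds matrices (must cover the watch
#'   motifs).
#' @param constraints A [DesignConstraints-class].
#' @param bg Background model.
#' @param cfg A [ScanConfig-class]; the constraint threshold overrides its
#'   `pThreshold`.
#' @param dists Optional precomputed score distributions.
#' @return A [VerificationReport-class].
#' @export
verifyVariant <- function(wildtype, variant, library, constraints,
                          bg = background(), cfg = scanConfig(),
                          dists = NULL) {
  wildtype <- toupper(as.character(wildtype))
  variant <- toupper(as.character(variant))
  if (nchar(wildtype) != nchar(variant))
    stop("wildtype and variant must have the same length")
  cfg@pThreshold <- constraints@pThreshold
  watch <- library[intersect(names(library), constraints@watchMotifIds)]
  if (is.null(dists)) dists <- .libDists(watch, bg, cfg)
  wt <- scanLibrary(wildtype, watch, bg, cfg, seqId = "wt",
                    dists = dists[names(watch)])
  vr <- scanLibrary(variant, watch, bg, cfg, seqId = "wt",
                    dists = dists[names(watch)])
  wtKeys <- .hitIds(wt); vrKeys <- .hitIds(vr)
  isTarget <- wt$motif_id %in% constraints@targetMotifIds
  surviving <- wt[isTarget & wtKeys %in% vrKeys, , drop = FALSE]
  lost <- wt[isTarget & !(wtKeys %in% vrKeys), , drop = FALSE]
  newHits <- vr[!(vrKeys %in% wtKeys), , drop = FALSE]
  protected <- constraints@protectedHits
  pKeys <- .hitIds(protected)
  lostProt <- protected[!(pKeys %in% vrKeys), , drop = FALSE]
  passed <- nrow(surviving) == 0 && nrow(newHits) == 0 &&
    all(.hitIds(lostProt) %in% constraints@allowedCollateral)
  new("VerificationReport", lostTargetHits = lost,
      survivingTargetHits = surviving, lostProtectedHits = lostProt,
      newHits = newHits, passed = passed)
}

#' Design a full knockout construct
#'
#' The multi-cycle design loop: scan the sequence for target-motif hits,
#' knock them out left to right (re-scanning after each edit so overlapping
#' target sites destroyed en passant are skipped), then verify the whole
#' variant by full rescan. If verification fails because an edit created or
#' destroyed a forbidden site, the offending substitution combinations are
#' excluded and the search resumes from the wildtype on the next cycle.
#'
#' @param seq Wildtype sequence.
#' @param constraints A [DesignConstraints-class].
#' @param library Named list of log-odds matrices covering target and watch
#'   motifs.
#' @param bg Background model.
#' @param cfg A [ScanConfig-class].
#' @param name Construct name for the resulting variant.
#' @param maxCycles Design/rescan cycles before declaring infeasibility.
#' @return An [EnhancerVariant-class] (verified, `passed` TRUE) or an
#'   [InfeasibilityRecord-class].
#' @export
designConstruct <- function(seq, constraints, library, bg = background(),
                            cfg = scanConfig(), name = "variant",
                            maxCycles = 5L) {
  seq <- toupper(as.character(seq))
  cfg@pThreshold <- constraints@pThreshold
  watch <- library[intersect(names(library), constraints@watchMotifIds)]
  dists <- .libDists(watch, bg, cfg)
  targets <- intersect(names(watch), constraints@targetMotifIds)

  wtTargetHits <- scanLibrary(seq, watch[targets], bg, cfg, seqId = "wt",
                              dists = dists[targets])
  if (nrow(wtTargetHits) == 0) {
    rep0 <- verifyVariant(seq, seq, watch, constraints, bg, cfg, dists)
    return(new("EnhancerVariant", name = name, sequence = seq,
               plan = mutationPlan(), report = rep0))
  }

  exclude <- list()
  for (cycle in seq_len(maxCycles)) {
    cur <- seq
    chosen <- list()  # hit key -> position key, for blame assignment
    allSub <- data.frame(position = integer(), ref = character(),
                         alt = character(), stringsAsFactors = FALSE)
    failed <- NULL
    for (i in seq_len(nrow(wtTargetHits))) {
      hit <- wtTargetHits[i, ]
      hkey <- .hitIds(hit)
      # skip hits already destroyed by earlier edits this cycle
      still <- .scanRegion(cur, hit$start, hit$end,
                           watch[hit$motif_id], bg, cfg,
                           dists[hit$motif_id])
      if (!any(still$start == hit$start & still$end == hit$end &
               still$strand == hit$strand)) next
      out <- designSiteKnockout(cur, hit, watch[[hit$motif_id]],
                                constraints, bg, cfg, watch, dists,
                                exclude = exclude[[hkey]] %||% character())
      if (is(out, "InfeasibilityRecord")) return(out)
      chosen[[hkey]] <- paste(out@substitutions$position, collapse = ",")
      allSub <- rbind(allSub, out@substitutions)
      cur <- applyPlan(cur, out)
    }
    report <- verifyVariant(seq, cur, watch, constraints, bg, cfg, dists)
    if (report@passed) {
      allSub <- allSub[order(allSub$position), , drop = FALSE]
      rownames(allSub) <- NULL
      plan <- new("MutationPlan", substitutions = allSub,
                  targetHitIds = .hitIds(wtTargetHits))
      return(new("EnhancerVariant", name = name, sequence = cur,
                 plan = plan, report = report))
    }
    # blame: exclude the combos of sites whose edits lie near the offenders
    offenders <- rbind(report@survivingTargetHits, report@newHits,
                       report@lostProtectedHits[
                         !(.hitIds(report@lostProtectedHits) %in%
                             constraints@allowedCollateral), , drop = FALSE])
    wmax <- .maxWidth(watch)
    blamed <- FALSE
    for (hkey in names(chosen)) {
      pos <- as.integer(strsplit(chosen[[hkey]], ",")[[1]])
      near <- any(offenders$end >= min(pos) - (wmax - 1L) &
                  offenders$start <= max(pos) + (wmax - 1L))
      if (near || nrow(offenders) == 0) {
        exclude[[hkey]] <- unique(c(exclude[[hkey]], chosen[[hkey]]))
        blamed <- TRUE
      }
    }
    if (!blamed) {
      for (hkey in names(chosen))
        exclude[[hkey]] <- unique(c(exclude[[hkey]], chosen[[hkey]]))
    }
  }
  new("InfeasibilityRecord", hitId = .hitIds(wtTargetHits),
      conflicts = data.frame(candidate = character(),
                             destroys = character(),
                             stringsAsFactors = FALSE),
      message = sprintf("no passing design found within %d cycles",
                        maxCycles))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
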