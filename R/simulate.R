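#' Configuration for a simulated enhancer sequence
#'
#' @param length Sequence length in bp; default 377, matching the proximal
#'   brachyury enhancer fragment the package is built around.
#' @param gcContent GC proportion of the i.i.d. background (default 0.4,
#'   a realistic value for AT-rich tunicate non-coding sequence).
#' @param plants data.frame with columns `motif_id`, `position`, `strand`
#'   and `mode` (`"consensus"` plants the column-maximum sequence,
#'   `"sample"` draws each base from the column frequencies). Later plants
#'   overwrite earlier ones where they overlap.
#' @param exclusionThreshold Background is resampled until no library motif
#'   hits at p <= this outside the planted intervals (default 1e-3).
#' @param seed RNG seed.
#' @param maxAttempts Resampling budget (default 200).
#' @return A [SequenceSimConfig-class].
#' @export
sequenceSimConfig <- function(length = 377L, gcContent = 0.4,
                              plants = data.frame(
                                motif_id = character(),
                                position = integer(),
                                strand = character(),
                                mode = character(),
                                stringsAsFactors = FALSE),
                              exclusionThreshold = 1e-3, seed = 1L,
                              maxAttempts = 200L) {
  new("SequenceSimConfig", length = as.integer(length),
      gcContent = gcContent, plants = plants,
      exclusionThreshold = exclusionThreshold, seed = as.integer(seed),
      maxAttempts = as.integer(maxAttempts))
}

.plantSequence <- function(pwm, mode) {
  if (mode == "consensus") return(consensusSequence(pwm))
  prob <- sweep(pwm@counts, 2, colSums(pwm@counts), "/")
  paste(vapply(seq_len(ncol(prob)), function(j)
    sample(DNA_BASES, 1, prob = prob[, j]), character(1)), collapse = "")
}

#' Generate a background enhancer with planted motif instances
#'
#' Draws an i.i.d. background sequence at the configured GC content, plants
#' the requested motif instances, and rejection-resamples the background
#' until no library motif matches at the exclusion threshold outside the
#' planted intervals, so that the planted sites are the complete ground
#' truth for scanner benchmarking.
#'
#' @param cfg A [SequenceSimConfig-class].
#' @param library Named list of [MotifMatrix-class] objects (the motifs to
#'   exclude from the background; plants refer to these by name).
#' @param bg Background used for the exclusion scan.
#' @return List with `sequence` (character), `truth` (data.frame of planted
#'   intervals with the planted subsequence) and `attempts`.
#' @export
generateEnhancer <- function(cfg, library, bg = background()) {
  set.seed(cfg@seed)
  L <- cfg@length
  plants <- cfg@plants
  loms <- lapply(library, pwmLogOdds, bg = bg)
  scfg <- scanConfig(pThreshold = cfg@exclusionThreshold)
  dists <- .libDists(loms, bg, scfg)

  plantSeqs <- character(nrow(plants))
  intervals <- NULL
  if (nrow(plants) > 0) {
    for (i in seq_len(nrow(plants))) {
      pwm <- library[[plants$motif_id[i]]]
      if (is.null(pwm))
        stop(sprintf("plant motif '%s' not in library", plants$motif_id[i]))
      ps <- .plantSequence(pwm, plants$mode[i])
      if (plants$strand[i] == "-")
        ps <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ps)))
      if (plants$position[i] < 1 ||
          plants$position[i] + nchar(ps) - 1L > L)
        stop(sprintf("plant %d does not fit in a %d bp sequence", i, L))
      plantSeqs[i] <- ps
    }
    intervals <- data.frame(
      motif_id = plants$motif_id,
      start = plants$position,
      end = plants$position + nchar(plantSeqs) - 1L,
      strand = plants$strand, planted_seq = plantSeqs,
      stringsAsFactors = FALSE)
  }
  p <- c((1 - cfg@gcContent) / 2, cfg@gcContent / 2,
         cfg@gcContent / 2, (1 - cfg@gcContent) / 2)

  for (attempt in seq_len(cfg@maxAttempts)) {
    chars <- sample(DNA_BASES, L, replace = TRUE, prob = p)
    if (!is.null(intervals))
      for (i in seq_len(nrow(intervals)))
        chars[intervals$start[i]:intervals$end[i]] <-
          strsplit(intervals$planted_seq[i], "")[[1]]
    seq <- paste(chars, collapse = "")
    hits <- scanLibrary(seq, loms, bg, scfg, seqId = "sim", dists = dists)
    if (nrow(hits) > 0 && !is.null(intervals)) {
      covered <- vapply(seq_len(nrow(hits)), function(h)
        any(hits$start[h] >= intervals$start &
              hits$end[h] <= intervals$end), logical(1))
      hits <- hits[!covered, , drop = FALSE]
    }
    if (nrow(hits) == 0)
      return(list(sequence = seq,
                  truth = if (is.null(intervals))
                    data.frame() else intervals,
                  attempts = attempt))
  }
  stop(sprintf(
    "no clean background in %d attempts; use a longer sequence or a looser exclusion threshold",
    cfg@maxAttempts))
}

#' Configuration for simulated dual-reporter measurements
#'
#' Defaults emulate the study conditions: 32 primary and 8 secondary
#' notochord cells per embryo, at least three replicates, substantial
#' embryo-to-embryo electroporation-efficiency variation (sdlog 1, which
#' the ratio normalization must cancel), per-cell multiplicative noise
#' (sdlog 1) and mosaicism 0.6, together giving a wildtype normalized-ratio
#' spread of roughly 0.5-2.
#'
#' @param constructs data.frame with columns `construct_id`, `strength`
#'   (reporter strength relative to wildtype), `mosaicism` (probability a
#'   cell takes up the plasmid mix) and `secondary_attenuation` (factor on
#'   reporter output in secondary-lineage cells).
#' @param nEmbryos Embryos per construct per replicate (default 12).
#' @param nReplicates Electroporation days (default 3).
#' @param efficiencySigma sdlog of per-embryo efficiency (default 1).
#' @param cellSigma sdlog of per-cell noise (default 1).
#' @param baseline Intensity of non-expressing cells (default 10).
#' @param cellsPrimary,cellsSecondary Lineage sizes (defaults 32 and 8).
#' @param controlStrength Mean control intensity of an expressing cell at
#'   unit efficiency (default 1000; on this scale the 256 single-cell
#'   threshold separates the expressing and baseline modes).
#' @param reporterScale Reporter intensity at strength 1 (default 2000).
#' @param correlatedUptake Both channels ride one uptake event (default
#'   TRUE: co-electroporated plasmids co-segregate).
#' @param wildtypeId Wildtype construct id (default "WT").
#' @param seed RNG seed.
#' @return An [ExpressionSimConfig-class].
#' @export
expressionSimConfig <- function(
    constructs = data.frame(construct_id = c("WT", "MUT"),
                            strength = c(1, 0.3), mosaicism = 0.6,
                            secondary_attenuation = 1,
                            stringsAsFactors = FALSE),
    nEmbryos = 12L, nReplicates = 3L, efficiencySigma = 1,
    cellSigma = 1, baseline = 10, cellsPrimary = 32L, cellsSecondary = 8L,
    controlStrength = 1000, reporterScale = 2000, correlatedUptake = TRUE,
    wildtypeId = "WT", seed = 1L) {
  new("ExpressionSimConfig", constructs = constructs,
      nEmbryos = as.integer(nEmbryos), nReplicates = as.integer(nReplicates),
      efficiencySigma = efficiencySigma, cellSigma = cellSigma,
      baseline = baseline, cellsPrimary = as.integer(cellsPrimary),
      cellsSecondary = as.integer(cellsSecondary),
      controlStrength = controlStrength, reporterScale = reporterScale,
      correlatedUptake = correlatedUptake, wildtypeId = wildtypeId,
      seed = as.integer(seed))
}

# per-cell draws for every embryo; single seeded generator drives everything
.simulateCellsCore <- function(cfg) {
  cs <- cfg@constructs
  nc <- cfg@cellsPrimary + cfg@cellsSecondary
  lineage <- c(rep("primary", cfg@cellsPrimary),
               rep("secondary", cfg@cellsSecondary))
  rows <- vector("list", nrow(cs) * cfg@nReplicates * cfg@nEmbryos)
  ri <- 0L
  for (rep_i in seq_len(cfg@nReplicates)) {
    for (ci in seq_len(nrow(cs))) {
      for (e in seq_len(cfg@nEmbryos)) {
        # exp(sigma * z) rather than rlnorm so the RNG stream is identical
        # across efficiencySigma settings (paired-seed comparisons)
        E <- exp(cfg@efficiencySigma * stats::rnorm(1))
        upControl <- stats::runif(nc) < cs$mosaicism[ci]
        upReporter <- if (cfg@correlatedUptake) upControl else
          stats::runif(nc) < cs$mosaicism[ci]
        att <- ifelse(lineage == "secondary",
                      cs$secondary_attenuation[ci], 1)
        repSignal <- cs$strength[ci] * cfg@reporterScale * att * E *
          stats::rlnorm(nc, 0, cfg@cellSigma)
        ctlSignal <- cfg@controlStrength * E *
          stats::rlnorm(nc, 0, cfg@cellSigma)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          cell_id = sprintf("r%d_%s_e%d_c%d", rep_i, cs$construct_id[ci],
                            e, seq_len(nc)),
          embryo_id = sprintf("r%d_%s_e%d", rep_i, cs$construct_id[ci], e),
          replicate_id = sprintf("rep%d", rep_i),
          construct_id = cs$construct_id[ci],
          lineage = lineage,
          reporter_mean = ifelse(upReporter, repSignal, cfg@baseline),
          control_mean = ifelse(upControl, ctlSignal, cfg@baseline),
          efficiency = E,
          expressing_reporter = upReporter,
          expressing_control = upControl,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate per-embryo dual-reporter measurements
#'
#' Runs the generative model of [expressionSimConfig()] and aggregates the
#' per-cell intensities to embryo-level ROI means (whole notochord and per
#' lineage), the same schema [normalizeExperiment()] consumes.
#'
#' @param cfg An [ExpressionSimConfig-class].
#' @return List with `measurements` (per-embryo data.frame), `cells`
#'   (the underlying per-cell ground truth) and `efficiencies`.
#' @export
simulateMeasurements <- function(cfg) {
  set.seed(cfg@seed)
  cells <- .simulateCellsCore(cfg)
  agg <- function(v, sel) tapply(v[sel], cells$embryo_id[sel], mean)
  ids <- unique(cells$embryo_id)
  pri <- cells$lineage == "primary"
  sec <- !pri
  all <- rep(TRUE, nrow(cells))
  meta <- cells[match(ids, cells$embryo_id),
                c("embryo_id", "replicate_id", "construct_id")]
  m <- data.frame(
    meta,
    reporter_mean = as.numeric(agg(cells$reporter_mean, all)[ids]),
    control_mean = as.numeric(agg(cells$control_mean, all)[ids]),
    reporter_primary = as.numeric(agg(cells$reporter_mean, pri)[ids]),
    control_primary = as.numeric(agg(cells$control_mean, pri)[ids]),
    reporter_secondary = as.numeric(agg(cells$reporter_mean, sec)[ids]),
    control_secondary = as.numeric(agg(cells$control_mean, sec)[ids]),
    stringsAsFactors = FALSE, row.names = NULL)
  eff <- cells[match(ids, cells$embryo_id),
               c("embryo_id", "efficiency")]
  rownames(eff) <- NULL
  list(measurements = m, cells = cells, efficiencies = eff)
}

#' Simulate per-cell measurements
#'
#' Per-cell rows from the same generative model, before embryo-level
#' averaging; the input schema of the single-cell analyses. The
#' pure-mosaicism and pure-graded archetypes are obtained by halving
#' `mosaicism` (at unchanged `strength`) or halving `strength` (at
#' unchanged `mosaicism`).
#'
#' @param cfg An [ExpressionSimConfig-class].
#' @return data.frame of per-cell measurements with ground-truth columns.
#' @export
simulateCells <- function(cfg) {
  set.seed(cfg@seed)
  .simulateCellsCore(cfg)
}

#' Render cells as a confocal-like stack with matching ROIs
#'
#' Places one Gaussian blob per cell in each channel, scaled so the blob's
#' (untruncated) integral equals the cell's channel intensity, with
#' optional Poisson noise; returns the stack, a rectangular whole-notochord
#' ROI enclosing all blobs, and the blob integrals as ground truth for
#' testing the projection/ROI quantitation chain.
#'
#' @param cells data.frame with columns `x`, `y`, `z`, `reporter`,
#'   `control`.
#' @param dims Volume as c(z, y, x).
#' @param sigma Blob standard deviation in voxels (default 2).
#' @param noise `"none"` or `"poisson"`.
#' @param margin ROI margin around the blob bounding box (default
#'   `4 * sigma`).
#' @return List with `stack` ([ImageStack-class]), `rois`
#'   ([ROISet-class]) and `truth` (the input intensities).
#' @export
renderStack <- function(cells, dims = c(8L, 48L, 48L), sigma = 2,
                        noise = c("none", "poisson"), margin = 4 * sigma) {
  noise <- match.arg(noise)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  mk <- function(col) {
    vol <- array(0, c(nz, ny, nx))
    for (i in seq_len(nrow(cells))) {
      gz <- stats::dnorm(seq_len(nz), cells$z[i], sigma)
      gy <- stats::dnorm(seq_len(ny), cells$y[i], sigma)
      gx <- stats::dnorm(seq_len(nx), cells$x[i], sigma)
      vol <- vol + cells[[col]][i] * outer(gz, outer(gy, gx))
    }
    if (noise == "poisson")
      vol[] <- stats::rpois(length(vol), vol)
    vol
  }
  stack <- imageStack(list(reporter = mk("reporter"),
                           control = mk("control")),
                      channelRoles = c(reporter = "reporter",
                                       control = "control"))
  if (nrow(cells) > 0) {
    xr <- range(cells$x) + c(-margin, margin)
    yr <- range(cells$y) + c(-margin, margin)
  } else {
    xr <- c(1, nx); yr <- c(1, ny)
  }
  xr <- pmin(pmax(xr, 0.5), nx + 0.5)
  yr <- pmin(pmax(yr, 0.5), ny + 0.5)
  poly <- cbind(x = c(xr[1], xr[2], xr[2], xr[1]),
                y = c(yr[1], yr[1], yr[2], yr[2]))
  list(stack = stack, rois = roiSet(poly), truth = cells)
}
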