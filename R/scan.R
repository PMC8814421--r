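#' Scanning configuration constructor
#'
#' @param pThreshold Match p-value threshold; a window is a hit iff its
#'   p-value is `<= pThreshold` (default 1e-3, the compromise threshold of
#'   the initial screen; 1e-2 was used for the follow-up of low-scoring
#'   ETS sites).
#' @param pseudocount Total pseudocount per column (default 0.1).
#' @param bothStrands Scan both strands (default TRUE).
#' @param gridResolution Bits per bin for exact p-values (default 0.001).
#' @return A [ScanConfig-class].
#' @export
scanConfig <- function(pThreshold = 1e-3, pseudocount = 0.1,
                       bothStrands = TRUE, gridResolution = 0.001) {
  new("ScanConfig", pThreshold = pThreshold, pseudocount = pseudocount,
      bothStrands = bothStrands, gridResolution = gridResolution)
}

.emptyHits <- function() {
  data.frame(motif_id = character(), seq_id = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), p_value = numeric(),
             matched_seq = character(), stringsAsFactors = FALSE)
}

#' Identity keys for motif hits
#'
#' `motif:start:end:strand` keys used to match hits across scans of the
#' same sequence (e.g. wildtype versus variant) and to name protected hits
#' in `allowedCollateral` lists. The sequence id is deliberately not part
#' of the key: verification always compares scans of one sequence.
#'
#' @param hits Hit data.frame.
#' @return Character vector of keys.
#' @export
hitKeys <- function(hits) {
  if (nrow(hits) == 0) return(character())
  paste(hits$motif_id, hits$start, hits$end, hits$strand, sep = ":")
}

.hitIds <- hitKeys

# binned window scores for every full window of an integer-encoded sequence;
# windows containing NA (non-ACGT) come back NA
.windowBins <- function(enc, bins) {
  w <- ncol(bins)
  n <- length(enc) - w + 1L
  if (n < 1L) return(integer(0))
  tot <- integer(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    b <- enc[j:(j + n - 1L)]
    na <- is.na(b)
    bad <- bad | na
    bj <- bins[, j][ifelse(na, 1L, b)]
    tot <- tot + bj
  }
  tot[bad] <- NA_integer_
  tot
}

#' Scan a sequence for motif matches
#'
#' Scores every window of the sequence (both strands if configured) against
#' a log-odds matrix and reports windows whose exact match p-value is at or
#' below the threshold, in forward-strand coordinates. Windows containing
#' non-ACGT characters are skipped. P-values are the exact DP tail of the
#' grid-discretized matrix, so results are deterministic and enumeration-
#' consistent; no multiple-testing correction is applied across positions
#' (hits are raw-threshold calls).
#'
#' @param seq Character scalar or [Biostrings::DNAString]; the sequence to
#'   scan.
#' @param lom A [LogOddsMatrix-class].
#' @param bg A [Background-class] (defaults to the matrix's own).
#' @param cfg A [ScanConfig-class].
#' @param seqId Sequence identifier recorded in the hit table.
#' @param dist Optional precomputed [ScoreDistribution-class] (must match
#'   `lom`, `bg` and `cfg@gridResolution`); avoids rebuilding in loops.
#' @return A data.frame with columns `motif_id`, `seq_id`, `start`, `end`
#'   (1-based inclusive, forward strand), `strand`, `score` (bits),
#'   `p_value`, `matched_seq` (always the forward-strand subsequence),
#'   sorted by start then strand.
#' @export
scanSequence <- function(seq, lom, bg = lom@background, cfg = scanConfig(),
                         seqId = "seq", dist = NULL) {
  stopifnot(is(lom, "LogOddsMatrix"), is(cfg, "ScanConfig"))
  s <- toupper(as.character(seq))
  L <- nchar(s)
  w <- ncol(lom@scores)
  if (L < w) return(.emptyHits())
  if (is.null(dist))
    dist <- scoreDistribution(lom, bg, grid = cfg@gridResolution)
  enc <- .encodeSequence(s)
  grid <- dist@grid

  collect <- function(enc_strand, strand) {
    tot <- .windowBins(enc_strand, dist@bins)
    pv <- rep(NA_real_, length(tot))
    ok <- !is.na(tot)
    pv[ok] <- .binnedPValue(dist, tot[ok])
    keep <- which(ok & pv <= cfg@pThreshold)
    if (length(keep) == 0) return(.emptyHits())
    if (strand == "+") {
      start <- keep
    } else {
      # window at position i of the reverse complement covers forward
      # positions [L - (i + w - 1) + 1, L - i + 1]
      start <- L - (keep + w - 1L) + 1L
    }
    data.frame(motif_id = lom@motifId, seq_id = seqId,
               start = start, end = start + w - 1L, strand = strand,
               score = tot[keep] * grid, p_value = pv[keep],
               matched_seq = substring(s, start, start + w - 1L),
               stringsAsFactors = FALSE)
  }

  hits <- collect(enc, "+")
  if (cfg@bothStrands) {
    rc <- rev(5L - enc)  # complement: A<->T, C<->G on the 1..4 encoding
    hits <- rbind(hits, collect(rc, "-"))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan with a whole motif library
#'
#' @param seq Sequence to scan.
#' @param library Named list of [LogOddsMatrix-class] objects.
#' @param bg Background model.
#' @param cfg A [ScanConfig-class].
#' @param seqId Sequence identifier.
#' @param dists Optional named list of precomputed score distributions.
#' @return Combined hit data.frame (see [scanSequence()]).
#' @export
scanLibrary <- function(seq, library, bg = background(), cfg = scanConfig(),
                        seqId = "seq", dists = NULL) {
  out <- lapply(names(library), function(id)
    scanSequence(seq, library[[id]], bg, cfg, seqId = seqId,
                 dist = if (is.null(dists)) NULL else dists[[id]]))
  res <- do.call(rbind, c(out, list(.emptyHits())))
  res <- res[order(res$start, res$strand, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair up overlapping hits from two hit tables
#'
#' Reports every pair of hits (one from each table, same sequence) whose
#' 1-based inclusive intervals share at least one position, annotated as
#' `full` (identical interval, or one contains the other) or `partial`.
#' This is how physically overlapping sites of core-sharing factors (e.g.
#' ETS and RBPJ over a common GGAA core) are identified.
#'
#' @param hitsA,hitsB Hit data.frames from [scanSequence()].
#' @return data.frame with the paired coordinates, motif ids and an
#'   `overlap` column ("full" or "partial").
#' @export
overlapPositions <- function(hitsA, hitsB) {
  empty <- data.frame(
    seq_id = character(), motif_a = character(), start_a = integer(),
    end_a = integer(), strand_a = character(), motif_b = character(),
    start_b = integer(), end_b = integer(), strand_b = character(),
    overlap = character(), stringsAsFactors = FALSE)
  if (nrow(hitsA) == 0 || nrow(hitsB) == 0) return(empty)
  out <- empty
  for (sid in intersect(unique(hitsA$seq_id), unique(hitsB$seq_id))) {
    a <- hitsA[hitsA$seq_id == sid, , drop = FALSE]
    b <- hitsB[hitsB$seq_id == sid, , drop = FALSE]
    ov <- IRanges::findOverlaps(IRanges::IRanges(a$start, a$end),
                                IRanges::IRanges(b$start, b$end))
    if (length(ov) == 0) next
    i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
    full <- (a$start[i] >= b$start[j] & a$end[i] <= b$end[j]) |
            (b$start[j] >= a$start[i] & b$end[j] <= a$end[i])
    out <- rbind(out, data.frame(
      seq_id = sid, motif_a = a$motif_id[i], start_a = a$start[i],
      end_a = a$end[i], strand_a = a$strand[i], motif_b = b$motif_id[j],
      start_b = b$start[j], end_b = b$end[j], strand_b = b$strand[j],
      overlap = ifelse(full, "full", "partial"), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write hits as FIMO-like TSV
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
writeHitsTSV <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export hits as BED6
#'
#' Coordinates are converted to the BED dialect (0-based half-open); the
#' BED score is `min(1000, round(-10 * log10(p)))`.
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
writeHitsBED <- function(hits, path) {
  bed <- data.frame(chrom = hits$seq_id,
                    chromStart = hits$start - 1L,
                    chromEnd = hits$end,
                    name = hits$motif_id,
                    score = pmin(1000, round(-10 * log10(pmax(
                      hits$p_value, 1e-300)))),
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert hits to a GRanges
#'
#' @param hits Hit data.frame.
#' @return A [GenomicRanges::GRanges] with score, p_value and motif_id
#'   metadata columns.
#' @export
hitsAsGRanges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$seq_id,
    ranges = IRanges::IRanges(hits$start, hits$end),
    strand = hits$strand,
    motif_id = hits$motif_id, score = hits$score, p_value = hits$p_value)
}
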