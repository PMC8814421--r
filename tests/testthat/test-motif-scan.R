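test_that("JASPAR blocks parse to count matrices with normalized row order", {
  txt <- c(">MA0001.1 TOY", "A [ 10 0 ]", "C [ 0 0 ]",
           "G [ 0 10 ]", "T [ 0 0 ]",
           ">MA0002.1 OTHER", "T [ 1 2 3 ]", "G [ 4 5 6 ]",
           "C [ 7 8 9 ]", "A [ 10 11 12 ]")
  pwms <- readJaspar(text = txt)
  expect_length(pwms, 2)
  expect_equal(motifId(pwms[[1]]), "MA0001.1")
  expect_equal(factorName(pwms[[1]]), "TOY")
  expect_equal(motifWidth(pwms[[1]]), 2)
  expect_equal(unname(motifCounts(pwms[[1]])["A", ]), c(10, 0))
  expect_equal(unname(motifCounts(pwms[[1]])["G", ]), c(0, 10))
  # labelled rows in scrambled order land on the right bases
  expect_equal(unname(motifCounts(pwms[[2]])["A", ]), c(10, 11, 12))
  expect_equal(unname(motifCounts(pwms[[2]])["T", ]), c(1, 2, 3))
})

test_that("bare (unlabelled) rows are taken in A,C,G,T order", {
  txt <- c(">M1 X", "3 0", "0 1", "1 2", "0 0")
  pwm <- readJaspar(text = txt)[[1]]
  expect_equal(unname(motifCounts(pwm)["A", ]), c(3, 0))
  expect_equal(unname(motifCounts(pwm)["C", ]), c(0, 1))
})

test_that("malformed JASPAR blocks raise errors naming the motif", {
  noT <- c(">MA0003.1 BAD", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]")
  expect_error(readJaspar(text = noT), "MA0003.1")
  ragged <- c(">MA0004.1 RAG", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]",
              "T [ 1 2 ]")
  expect_error(readJaspar(text = ragged), "ragged")
  dupRow <- c(">MA0005.1 DUP", "A [ 1 ]", "A [ 1 ]", "G [ 1 ]", "T [ 1 ]")
  expect_error(readJaspar(text = dupRow), "MA0005.1")
})

test_that("log-odds conversion matches the FIMO-style formula", {
  uniform <- new("MotifMatrix", motifId = "u", factorName = "",
                 counts = matrix(25, 4, 3,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL)))
  lom <- pwmLogOdds(uniform, pseudocount = 0.1)
  expect_true(all(abs(lomScores(lom)) < 1e-10))

  onehot <- new("MotifMatrix", motifId = "oh", factorName = "",
                counts = matrix(c(100, 0, 0, 0), 4, 1,
                                dimnames = list(c("A", "C", "G", "T"),
                                                NULL)))
  lo <- pwmLogOdds(onehot, pseudocount = 0.1)
  # hand arithmetic: log2((100.025/100.1)/0.25)
  expect_equal(unname(lomScores(lo)["A", 1]),
               log2((100 + 0.1 * 0.25) / 100.1 / 0.25), tolerance = 1e-12)
  expect_equal(unname(lomScores(lo)["A", 1]), 1.9989, tolerance = 1e-4)

  expect_error(pwmLogOdds(onehot, pseudocount = 0), "pseudocount")
})

test_that("the tallest logo base carries the column maximum score", {
  for (pwm in list(etsExampleMotif(), rbpjExampleMotif())) {
    lom <- pwmLogOdds(pwm)
    tallest <- apply(motifCounts(pwm), 2, which.max)
    best <- apply(lomScores(lom), 2, which.max)
    expect_equal(best, tallest)
  }
})

test_that("window scoring sums per-position log odds", {
  lom <- toyLogOdds()
  expect_equal(scoreWindow(lom, "AG"), 2 * log2(2.8), tolerance = 1e-12)
  expect_equal(scoreWindow(lom, "AG"), 2.9708, tolerance = 1e-4)
  zero <- probsToLogOdds(matrix(0.25, 4, 3))
  expect_equal(scoreWindow(zero, "ACG"), 0)
  expect_equal(scoreWindow(lom, consensusSequence(lom)),
               unname(scoreRange(lom)["max"]))
  expect_error(scoreWindow(lom, "AN"), "non-ACGT")
  expect_error(scoreWindow(lom, "AGG"), "length")
})

test_that("exact p-values match dinucleotide enumeration on the toy matrix", {
  lom <- toyLogOdds()
  dist <- scoreDistribution(lom)
  expect_equal(scorePValue(dist, scoreRange(lom)["min"]), 1)
  # only AG attains the maximum: 0.25 * 0.25
  expect_equal(scorePValue(dist, scoreRange(lom)["max"]), 0.0625)
  # score of "GG" (the A->G knockout of "AG"): 7 of 16 windows score >= it
  expect_equal(scorePValue(dist, scoreWindow(lom, "GG")), 7 / 16)
  # clamping outside the attainable range
  expect_equal(scorePValue(dist, -100), 1)
  expect_equal(scorePValue(dist, 100), 0)
})

test_that("DP tail equals exhaustive enumeration for random motifs", {
  set.seed(401)
  for (rep_i in 1:6) {
    w <- sample(2:6, 1)
    bg <- if (rep_i %% 2 == 0) background() else
      background(0.3, 0.2, 0.2, 0.3)
    lom <- pwmLogOdds(randomMotif(w), bg = bg)
    dist <- scoreDistribution(lom, bg)
    enum <- enumerateWindows(lom, bg)
    # binned scores: DP tail equals enumeration exactly
    kb <- round(lomScores(lom) / dist@grid)
    tot <- integer(nrow(enum$colScores))
    idx <- as.matrix(expand.grid(rep(list(1:4), w)))
    for (j in seq_len(w)) tot <- tot + unname(kb[idx[, j], j])
    enumBinned <- vapply(tot, function(k) sum(enum$prob[tot >= k]),
                         numeric(1))
    dpBinned <- enhancerDissect:::.binnedPValue(dist, as.integer(tot))
    expect_equal(dpBinned, enumBinned, tolerance = 1e-9)
    # raw-score queries: rounding the summed score moves it by at most
    # w/2 + 1 bins, so the DP answer sits between those enumeration tails
    s <- sort(unique(enum$scores))
    dp <- scorePValue(dist, s)
    slack <- (w / 2 + 1) * dist@grid
    lo <- enumTail(enum, s + slack)
    hi <- enumTail(enum, s - slack)
    expect_true(all(dp >= lo - 1e-9 & dp <= hi + 1e-9))
  }
})

test_that("tail probabilities are monotone with unit mass at the minimum", {
  set.seed(402)
  lom <- pwmLogOdds(randomMotif(7))
  dist <- scoreDistribution(lom)
  expect_equal(dist@tail[1], 1)
  expect_true(all(diff(dist@tail) <= 1e-12))
})

test_that("scanning finds planted consensus hits in forward coordinates", {
  lom <- toyLogOdds()
  expect_equal(nrow(scanSequence("A", lom)), 0)  # shorter than width
  s <- plantedToySequence()
  hits <- scanSequence(s, lom, cfg = scanConfig(pThreshold = 0.1))
  planted <- hits[hits$start == 20 & hits$strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$end, 21)
  expect_equal(planted$p_value, 0.0625)
  expect_equal(planted$matched_seq, "AG")
})

test_that("windows containing non-ACGT characters are skipped", {
  lom <- toyLogOdds()
  hits <- scanSequence("TTANGTT", lom, cfg = scanConfig(pThreshold = 1))
  expect_false(any(hits$start %in% c(3, 4)))  # windows touching the N
  expect_true(all(hits$p_value <= 1))
})

test_that("scanning the reverse complement mirrors hits with flipped strands", {
  set.seed(403)
  lom <- pwmLogOdds(randomMotif(5))
  seq <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  cfg <- scanConfig(pThreshold = 0.05)
  fwd <- scanSequence(seq, lom, cfg = cfg)
  rev <- scanSequence(revcomp(seq), lom, cfg = cfg)
  L <- nchar(seq)
  mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         p_value = rev$p_value)
  o1 <- order(fwd$start, fwd$strand)
  o2 <- order(mirrored$start, mirrored$strand)
  expect_equal(fwd$start[o1], mirrored$start[o2])
  expect_equal(fwd$strand[o1], mirrored$strand[o2])
  expect_equal(fwd$p_value[o1], mirrored$p_value[o2])
})

test_that("hit sets are nested across p-value thresholds", {
  set.seed(404)
  lom <- pwmLogOdds(randomMotif(6))
  seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  keys <- function(th) {
    h <- scanSequence(seq, lom, cfg = scanConfig(pThreshold = th))
    paste(h$start, h$strand)
  }
  k3 <- keys(1e-3); k2 <- keys(1e-2); k1 <- keys(1e-1)
  expect_true(all(k3 %in% k2))
  expect_true(all(k2 %in% k1))
})

test_that("overlapPositions pairs intersecting hits and grades the overlap", {
  mk <- function(motif, start, end, strand = "+", seq_id = "s") {
    data.frame(motif_id = motif, seq_id = seq_id, start = start, end = end,
               strand = strand, score = 0, p_value = 0.001,
               matched_seq = "", stringsAsFactors = FALSE)
  }
  expect_equal(nrow(overlapPositions(mk("a", 1, 5), mk("b", 10, 14))), 0)
  partial <- overlapPositions(mk("a", 10, 17), mk("b", 12, 19))
  expect_equal(nrow(partial), 1)
  expect_equal(partial$overlap, "partial")
  nested <- overlapPositions(mk("a", 12, 15), mk("b", 10, 19))
  expect_equal(nested$overlap, "full")
  identical_iv <- overlapPositions(mk("a", 10, 17), mk("b", 10, 17))
  expect_equal(identical_iv$overlap, "full")
  # different sequences never pair
  expect_equal(nrow(overlapPositions(mk("a", 1, 5, seq_id = "s1"),
                                     mk("b", 1, 5, seq_id = "s2"))), 0)
})

test_that("hits export to TSV, BED (0-based half-open) and GRanges", {
  lom <- toyLogOdds()
  hits <- scanSequence(plantedToySequence(), lom,
                       cfg = scanConfig(pThreshold = 0.1))
  tsv <- tempfile(fileext = ".tsv")
  writeHitsTSV(hits, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$start, hits$start)
  bed <- tempfile(fileext = ".bed")
  writeHitsBED(hits, bed)
  bedtab <- utils::read.delim(bed, header = FALSE)
  expect_equal(bedtab$V2, hits$start - 1L)
  expect_equal(bedtab$V3, hits$end)
  gr <- hitsAsGRanges(hits)
  expect_equal(GenomicRanges::start(gr), hits$start)
  expect_equal(GenomicRanges::width(gr)[1], 2L)
})
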