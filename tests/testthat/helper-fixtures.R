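# shared fixtures: toy matrices and independent oracles

# width-2 toy: col1 favors A (0.7), col2 favors G (0.7); uniform background
toyLogOdds <- function() {
  probsToLogOdds(matrix(c(0.7, 0.1, 0.1, 0.1,
                          0.1, 0.1, 0.7, 0.1), nrow = 4), motifId = "toy")
}

# near-one-hot GGAA core motif (shared core of ETS/RBPJ-style factors)
coreMotif <- function() {
  new("MotifMatrix", motifId = "CORE_demo", factorName = "GGAA-core",
      counts = matrix(c(1, 1, 97, 1,
                        1, 1, 97, 1,
                        97, 1, 1, 1,
                        92, 3, 3, 2), nrow = 4,
                      dimnames = list(c("A", "C", "G", "T"), NULL)))
}

randomMotif <- function(width, id = "rnd") {
  counts <- matrix(stats::rgamma(4 * width, shape = 1) * 20 + 0.5, 4, width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  new("MotifMatrix", motifId = id, factorName = "", counts = counts)
}

# exhaustive enumeration oracle: all 4^width windows, their exact scores
# and background probabilities -- independent of the DP implementation
enumerateWindows <- function(lom, bg = background()) {
  w <- ncol(lomScores(lom))
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- matrix(0, nrow(idx), w)
  for (j in seq_len(w)) sc[, j] <- lomScores(lom)[idx[, j], j]
  prob <- rep(1, nrow(idx))
  for (j in seq_len(w)) prob <- prob * bgProbs(bg)[idx[, j]]
  list(scores = rowSums(sc), colScores = sc, prob = prob)
}

# enumeration tail probability P(score >= s) from the oracle
enumTail <- function(enum, s) {
  vapply(s, function(si) sum(enum$prob[enum$scores >= si - 1e-12]),
         numeric(1))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# a 50-nt sequence with a single planted toy-consensus "AG" at position 20
# and no incidental toy hits (all-T elsewhere: no AG or CT windows)
plantedToySequence <- function() {
  paste0(strrep("T", 19), "AG", strrep("T", 29))
}

# clean background with planted ETS-demo consensus sites
plantedEtsEnhancer <- function(positions, strands, seed, length = 377L,
                               exclusion = 1e-3) {
  lib <- list(ETS_demo = etsExampleMotif())
  cfg <- sequenceSimConfig(
    length = length,
    plants = data.frame(motif_id = "ETS_demo", position = positions,
                        strand = strands, mode = "consensus",
                        stringsAsFactors = FALSE),
    exclusionThreshold = exclusion, seed = seed)
  generateEnhancer(cfg, lib)
}
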