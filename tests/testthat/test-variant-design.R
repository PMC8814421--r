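test_that("transition substitution preserves purine/pyrimidine class", {
  expect_equal(transitionBase("A"), "G")
  expect_equal(transitionBase("G"), "A")
  expect_equal(transitionBase("C"), "T")
  expect_equal(transitionBase("T"), "C")
  for (b in c("A", "C", "G", "T"))
    expect_equal(transitionBase(transitionBase(b)), b)
  expect_error(transitionBase("N"), "transition")
})

test_that("columns rank by information content with leftmost tie-break", {
  onehot_first <- new("MotifMatrix", motifId = "m", factorName = "",
                      counts = matrix(c(100, 0, 0, 0, 25, 25, 25, 25),
                                      4, 2,
                                      dimnames = list(c("A", "C", "G", "T"),
                                                      NULL)))
  expect_equal(rankPositions(onehot_first), c(1L, 2L))
  allflat <- new("MotifMatrix", motifId = "f", factorName = "",
                 counts = matrix(10, 4, 4,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL)))
  expect_equal(rankPositions(allflat), 1:4)
  # direct-IC oracle on a 3-column matrix with distinct column entropies
  cols <- cbind(c(40, 20, 20, 20), c(97, 1, 1, 1), c(50, 50, 0, 0))
  rownames(cols) <- c("A", "C", "G", "T")
  pwm <- new("MotifMatrix", motifId = "ic3", factorName = "", counts = cols)
  directIC <- apply(cols, 2, function(cl) {
    p <- cl / sum(cl); p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  expect_equal(rankPositions(pwm), order(-directIC))
  expect_equal(rankPositions(pwm), c(2L, 3L, 1L))
})

test_that("mutation plans apply as pure substitutions and invert exactly", {
  expect_equal(applyPlan("TTATT", mutationPlan()), "TTATT")
  plan <- mutationPlan(3L, "A", "G")
  expect_equal(applyPlan("TTATT", plan), "TTGTT")
  expect_error(applyPlan("TTCTT", plan), "ref mismatch")
  # involution property on random sequences and random transition plans
  set.seed(51)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    pos <- sort(sample(60, 5))
    ref <- substring(s, pos, pos)
    plan <- mutationPlan(pos, ref, vapply(ref, transitionBase,
                                          character(1)))
    v <- applyPlan(s, plan)
    expect_equal(nchar(v), nchar(s))
    expect_equal(applyPlan(v, invertPlan(plan)), s)
  }
})

test_that("a planted toy site is knocked out by a single ranked transition", {
  lom <- toyLogOdds()
  s <- plantedToySequence()
  cfg <- scanConfig(pThreshold = 0.1)
  hits <- scanSequence(s, lom, cfg = cfg)
  hit <- hits[hits$start == 20 & hits$strand == "+", ]
  cons <- designConstraints("toy", kMax = 2L, pThreshold = 0.1)
  plan <- designSiteKnockout(s, hit, lom, cons, background(), cfg,
                             library = list(toy = lom))
  expect_s4_class(plan, "MutationPlan")
  sub <- planSubstitutions(plan)
  expect_equal(nrow(sub), 1)
  expect_equal(sub$position, 20L)
  expect_equal(sub$ref, "A")
  expect_equal(sub$alt, "G")
  # the mutated window scores p = 7/16, above the 0.1 threshold
  v <- applyPlan(s, plan)
  d <- scoreDistribution(lom)
  expect_equal(scorePValue(d, scoreWindow(lom, substring(v, 20, 21))),
               0.4375)
})

test_that("a target nested in an identical protected site is infeasible", {
  lom <- toyLogOdds()
  lom2 <- toyLogOdds(); lom2@motifId <- "toy2"
  s <- plantedToySequence()
  cfg <- scanConfig(pThreshold = 0.1)
  hit <- scanSequence(s, lom, cfg = cfg)
  hit <- hit[hit$start == 20 & hit$strand == "+", ]
  prot <- scanSequence(s, lom2, cfg = cfg, seqId = "seq")
  prot <- prot[prot$start == 20 & prot$strand == "+", ]
  cons <- designConstraints("toy", watchMotifIds = c("toy", "toy2"),
                            protectedHits = prot, kMax = 2L,
                            pThreshold = 0.1)
  out <- designSiteKnockout(s, hit, lom, cons, background(), cfg,
                            library = list(toy = lom, toy2 = lom2))
  expect_s4_class(out, "InfeasibilityRecord")
  expect_true(nrow(out@conflicts) > 0)
  protKey <- paste("toy2", 20, 21, "+", sep = ":")
  expect_true(protKey %in% out@conflicts$destroys)
})

test_that("allowed collateral lets a design pass despite a lost protected site", {
  lom <- toyLogOdds()
  lom2 <- toyLogOdds(); lom2@motifId <- "toy2"
  s <- plantedToySequence()
  cfg <- scanConfig(pThreshold = 0.1)
  hit <- scanSequence(s, lom, cfg = cfg)
  hit <- hit[hit$start == 20 & hit$strand == "+", ]
  prot <- scanSequence(s, lom2, cfg = cfg, seqId = "seq")
  prot <- prot[prot$start == 20 & prot$strand == "+", ]
  protKey <- paste("toy2", 20, 21, "+", sep = ":")
  cons <- designConstraints("toy", watchMotifIds = c("toy", "toy2"),
                            protectedHits = prot,
                            allowedCollateral = protKey, kMax = 2L,
                            pThreshold = 0.1)
  lib <- list(toy = lom, toy2 = lom2)
  plan <- designSiteKnockout(s, hit, lom, cons, background(), cfg,
                             library = lib)
  expect_s4_class(plan, "MutationPlan")
  v <- applyPlan(s, plan)
  rep <- verifyVariant(s, v, lib, cons, background(), cfg)
  expect_true(rep@passed)
  expect_true(protKey %in% hitKeys(rep@lostProtectedHits))
})

test_that("verification fails when the variant equals the wildtype", {
  ets <- pwmLogOdds(etsExampleMotif())
  g <- plantedEtsEnhancer(positions = 100, strands = "+", seed = 42)
  cons <- designConstraints("ETS_demo")
  rep <- verifyVariant(g$sequence, g$sequence, list(ETS_demo = ets), cons)
  expect_false(rep@passed)
  expect_equal(nrow(rep@survivingTargetHits), 1)
  expect_equal(nrow(rep@newHits), 0)
})

test_that("designConstruct on a hit-free sequence returns the wildtype", {
  ets <- pwmLogOdds(etsExampleMotif())
  g <- generateEnhancer(sequenceSimConfig(length = 150L, seed = 7),
                        list(ETS_demo = etsExampleMotif()))
  v <- designConstruct(g$sequence, designConstraints("ETS_demo"),
                       list(ETS_demo = ets))
  expect_s4_class(v, "EnhancerVariant")
  expect_equal(variantSequence(v), g$sequence)
  expect_equal(nrow(planSubstitutions(v)), 0)
  expect_true(verificationPassed(v))
})

test_that("two well-separated planted sites are both knocked out", {
  ets <- pwmLogOdds(etsExampleMotif())
  g <- plantedEtsEnhancer(positions = c(60, 220), strands = c("+", "-"),
                          seed = 11)
  cons <- designConstraints("ETS_demo")
  v <- designConstruct(g$sequence, cons, list(ETS_demo = ets),
                       name = "ETSko")
  expect_s4_class(v, "EnhancerVariant")
  expect_true(verificationPassed(v))
  sub <- planSubstitutions(v)
  expect_lte(nrow(sub), 8)
  expect_equal(nchar(variantSequence(v)), nchar(g$sequence))
  # substitutions only: the variant differs exactly at the plan positions
  diffs <- which(strsplit(variantSequence(v), "")[[1]] !=
                   strsplit(g$sequence, "")[[1]])
  expect_equal(diffs, sub$position)
  # independent rescan with a fresh scanner reproduces the verdict
  hits <- scanSequence(variantSequence(v), ets,
                       cfg = scanConfig(pThreshold = cons@pThreshold))
  expect_equal(nrow(hits), 0)
})

test_that("designs are deterministic", {
  ets <- pwmLogOdds(etsExampleMotif())
  g <- plantedEtsEnhancer(positions = c(80, 200), strands = c("+", "+"),
                          seed = 23)
  cons <- designConstraints("ETS_demo")
  v1 <- designConstruct(g$sequence, cons, list(ETS_demo = ets))
  v2 <- designConstruct(g$sequence, cons, list(ETS_demo = ets))
  expect_identical(variantSequence(v1), variantSequence(v2))
  expect_identical(planSubstitutions(v1), planSubstitutions(v2))
})

test_that("mutually overlapping target/protected sites yield an infeasibility record", {
  lom <- toyLogOdds()
  lom2 <- toyLogOdds(); lom2@motifId <- "toy2"
  s <- plantedToySequence()
  cfg <- scanConfig(pThreshold = 0.1)
  prot <- scanSequence(s, lom2, cfg = cfg, seqId = "wt")
  prot <- prot[prot$start == 20 & prot$strand == "+", ]
  cons <- designConstraints("toy", watchMotifIds = c("toy", "toy2"),
                            protectedHits = prot, kMax = 2L,
                            pThreshold = 0.1)
  out <- designConstruct(s, cons, list(toy = lom, toy2 = lom2),
                         cfg = cfg)
  expect_s4_class(out, "InfeasibilityRecord")
})

test_that("passed variants never retain target hits across a seeded sweep", {
  ets <- pwmLogOdds(etsExampleMotif())
  lib <- list(ETS_demo = ets)
  cons <- designConstraints("ETS_demo")
  for (seed in 1:10) {
    set.seed(seed + 600)
    nsites <- sample(3:4, 1)
    gap <- floor(370 / nsites)
    positions <- (seq_len(nsites) - 1) * gap +
      sample(10, nsites, replace = TRUE)
    strands <- sample(c("+", "-"), nsites, replace = TRUE)
    g <- plantedEtsEnhancer(positions, strands, seed = seed + 600)
    v <- designConstruct(g$sequence, cons, lib)
    expect_s4_class(v, "EnhancerVariant")
    expect_true(verificationPassed(v))
    expect_equal(nchar(variantSequence(v)), 377)
    hits <- scanSequence(variantSequence(v), ets,
                         cfg = scanConfig(pThreshold = 1e-3))
    expect_equal(nrow(hits), 0)
  }
})
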