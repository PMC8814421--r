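# enhancerDissect

Quantitative cis-regulatory dissection of compact developmental enhancers,
built around the proximal enhancer of the notochord master regulator
*brachyury* in the ascidian *Ciona* (a 377-bp fragment,
KhS1404:5981–6357). The package is aimed at researchers running
image-based dual-reporter assays in electroporated embryos who want the
computational side of such a study — site prediction, mutant design and
quantitation — as tested, reusable code.

It implements four analysis stages plus seeded simulators:

* **Motif scanning with exact p-values.** JASPAR-format count matrices are
  converted to log2-odds scores
  `s(b,j) = log2(((c_bj + κ·p_b)/(C_j + κ)) / p_b)` against an i.i.d.
  background, and every sequence window (both strands) is assigned the
  exact match p-value `P(S ≥ s)` computed by dynamic-programming
  convolution of the per-column score distributions on a 1/1000-bit grid.
  A window is a TFBS hit iff `p ≤ threshold` (default 1e-3; 1e-2 for
  chasing low-scoring sites). Exhaustive enumeration of all 4^w windows is
  kept as the test oracle.
* **Knockout design.** Transition substitutions only (A↔G, C↔T),
  searched by iterative deepening (k = 1..4) over positions ranked by
  column information content, under constraints: every window overlapping
  the target site must rise above the p-value threshold on both strands,
  protected overlapping sites must survive at identical coordinates (or be
  explicitly allowed as collateral), no new site of any watched factor may
  appear, and construct length never changes. Designs are verified by full
  rescan; infeasible sites are reported with their conflict sets.
* **Dual-reporter quantitation.** Sum projection of confocal stacks,
  polygon-ROI means (pixel-center, even-odd rule), per-embryo
  reporter/control ratios that cancel electroporation efficiency,
  per-replicate normalization to the wildtype mean (exactly 1 per
  replicate), primary/secondary lineage ratios (anterior 32 vs posterior
  8 notochord cells), and pooled-SD pairwise t tests with
  Benjamini–Hochberg adjustment.
* **Single-cell analysis.** Cells split by internal-control intensity at
  a strict threshold of 256 (8 in log2 units), reporter-on-control
  regression, and a two-number decomposition of expression loss into
  mosaicism (expressing fraction) versus graded decrease (conditional
  log2 reporter/control ratio).
* **Synthetic data.** Seeded generators for background sequences with
  planted motif instances (rejection-sampled so plants are the complete
  ground truth), per-embryo/per-cell dual-reporter intensity tables with
  lognormal efficiency and cell noise plus per-cell mosaicism, and
  renderable Gaussian-blob image stacks with matching ROIs.

See `vignettes/enhancer-dissection-methods.Rmd` for the model details and
the reasoning behind every default.

## Worked example

```r
library(enhancerDissect)

ets <- etsExampleMotif()                       # stylized ETS-family matrix
lom <- pwmLogOdds(ets, background(), pseudocount = 0.1)
lom
#> LogOddsMatrix ETS_demo: width 9, score range [-25.052, 14.798] bits

# a synthetic 377-bp enhancer with two planted consensus sites
g <- generateEnhancer(
  sequenceSimConfig(
    plants = data.frame(motif_id = "ETS_demo", position = c(60, 220),
                        strand = c("+", "-"), mode = "consensus"),
    seed = 11),
  list(ETS_demo = ets))
scanSequence(g$sequence, lom, cfg = scanConfig(pThreshold = 1e-3))
#>   motif_id seq_id start end strand  score      p_value matched_seq
#> 1 ETS_demo    seq    60  68      + 14.799 3.814697e-06   ACCGGAAGT
#> 2 ETS_demo    seq   220 228      - 14.799 3.814697e-06   ACTTCCGGT

# design a knockout construct: both sites destroyed, length unchanged
variant <- designConstruct(g$sequence, designConstraints("ETS_demo"),
                           list(ETS_demo = lom), name = "ETS-KO")
variant
#> EnhancerVariant 'ETS-KO': 377 bp, 4 substitution(s), verified
planSubstitutions(variant)
#>   position ref alt
#> 1       63   G   A
#> 2       64   G   A
#> 3      223   T   C
#> 4      224   C   T

# dual-reporter simulation: wildtype vs a construct at 30% strength
sim <- simulateMeasurements(expressionSimConfig(
  constructs = data.frame(construct_id = c("WT", "ZIC"),
                          strength = c(1, 0.3), mosaicism = 0.6,
                          secondary_attenuation = 1),
  nEmbryos = 12, nReplicates = 3, seed = 1))
nt <- normalizeExperiment(sim$measurements, "WT")
round(tapply(nt$normalized_ratio, nt$construct_id, mean), 3)
#>    WT   ZIC
#> 1.000 0.302

pairwiseTests(nt$normalized_ratio, nt$construct_id)
#>   group1 group2       t df        raw_p   adjusted_p stars
#> 1     WT    ZIC 11.3605 70 1.522787e-17 1.522787e-17   ***
```

The mutated positions sit in the GGAA core (the highest-information
columns of the matrix), the wildtype mean is anchored at exactly 1, and
the simulated 0.3-strength construct is recovered at 0.302 — the
electroporation-efficiency noise (sdlog 1) has cancelled out of the
ratios.

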