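---
title: "Methods: quantitative dissection of a notochord enhancer"
author: "enhancerDissect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative dissection of a notochord enhancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerDissect)
```

## The problem

Compact developmental enhancers, such as the 377-bp proximal enhancer of
the notochord master regulator *brachyury* in the ascidian *Ciona*, are
dissected by predicting transcription factor binding sites (TFBSs),
mutating them, and measuring reporter expression in electroporated
embryos. Three quantitative problems recur:

1. **Site prediction.** Which sequence windows count as binding sites for
   a factor, given a binding-preference matrix and an arbitrary
   statistical threshold?
2. **Knockout design.** How do you mutate a site so that only that site is
   destroyed — no overlapping site of another factor of interest is lost,
   no new site is created, and the construct length is unchanged?
3. **Quantitation.** How do you compare reporter output across embryos and
   electroporations when delivery efficiency varies severalfold, and how
   do you tell fewer-expressing-cells (mosaicism) from
   less-expression-per-cell (graded loss)?

This package implements all three stages plus seeded generators that
produce inputs with the statistical structure the analyses assume, so that
every stage can be tested against ground truth.

## Motif scanning with exact p-values

A motif is a count matrix (JASPAR dialect; `readJaspar()`). Scoring
converts counts to log2 odds against an i.i.d. background
(`pwmLogOdds()`):

$$ s(b, j) = \log_2 \frac{(c_{bj} + \kappa\, p_b) / (C_j + \kappa)}{p_b} $$

with total pseudocount $\kappa$ (default 0.1) distributed by background
probability $p_b$. A window's score is the sum of its per-position terms;
its match p-value is $P(S \ge s)$ for a single random background window.
We compute this exactly by dynamic programming: each column's four scores
are rounded to a grid (default 1/1000 bit) and the distribution of the
total is built by positionwise convolution (`scoreDistribution()`).
Crucially, the scanner (`scanSequence()`) sums the *rounded* column scores
per window and reads the p-value straight off the DP tail, so scan
p-values agree exactly with exhaustive enumeration of all $4^w$ windows of
the discretized matrix — the test suite checks this against an independent
enumeration oracle for widths up to 8. Raw-score queries through
`scorePValue()` are rounded once and are accurate to within about
$w/2 + 1$ grid bins, i.e. a few thousandths of a bit.

Decisions worth stating explicitly:

* **Background** defaults to uniform (0.25 each) because the true genomic
  background of the scanned fragment is rarely known and uniform is
  reproducible; `backgroundFromSequence()` estimates a zero-order model
  from the scanned sequence when preferred.
* **A hit is `p <= threshold`**, with 1e-3 the default (a deliberate
  compromise: low enough to give a manageable list of strong-but-inexact
  matches, high enough not to return nothing) and 1e-2 the conventional
  relaxed setting for chasing low-scoring sites. Hit sets are nested
  across thresholds by construction.
* **No multiple-testing correction across positions** — hits are
  raw-threshold calls, matching how such scans are used in enhancer
  dissection.
* **Windows containing non-ACGT characters are skipped**, not
  ambiguity-averaged.
* **Coordinates are 1-based inclusive on the forward strand** everywhere
  in R; only the BED export converts to 0-based half-open.

## Knockout design under constraints

Mutations are **transition substitutions only** (A↔G, C↔T): preserving
purine/pyrimidine identity disrupts both palindromic and non-palindromic
motifs and keeps the edit maximally conservative. "Important" motif
positions are operationalized as the columns with the highest information
content (`rankPositions()`); ties break leftmost so the search is total
and deterministic.

`designSiteKnockout()` runs iterative deepening over the number of edits
$k = 1..k_{max}$ (default 4, since sites typically fall to two to four
substitutions), trying $k$-subsets ordered by summed information content.
A candidate passes when

* no window overlapping the original hit interval — on either strand —
  retains a target p-value at or below the threshold (stricter than
  killing only the original frame: a shifted window could survive);
* every protected hit touched by the edit survives at identical
  coordinates and strand with p still at or below threshold (its score may
  change: the criterion is site survival, not unchanged affinity), unless
  it is listed as allowed collateral — which is exactly how a
  low-scoring-ETS-style construct that sacrifices overlapping RBPJ sites
  is expressed;
* no new hit of any watch motif appears near the edit.

If no candidate passes, an `InfeasibilityRecord` reports, for each
candidate that did destroy the target, which protected hits it would have
lost. `designConstruct()` iterates over all target hits left to right,
rescanning after each edit, then verifies the whole variant by full rescan
(`verifyVariant()`); if a long-range interaction between two edits creates
or destroys a forbidden site, the offending combinations are excluded and
the search resumes from the wildtype — the multi-cycle design loop.
Variants never change length, and applying a plan followed by its inverse
restores the wildtype exactly.

## Dual-reporter quantitation

Stacks are flattened by **sum projection** (`sumProject()`), which
conserves total intensity, and quantified as the **mean** intensity inside
a manually drawn polygon (`roiMean()`; pixel-center, even-odd rule —
deterministic and standard). The mean is used rather than the integral:
both appear in descriptions of this kind of assay, but the mean is
invariant to how generously the ROI is padded over uniform background,
which matches the ratio semantics. No background subtraction is applied by
default.

Each embryo's expression value is reporter mean over internal-control mean
(`embryoRatio()`): any per-embryo multiplicative factor — electroporation
efficiency above all — cancels. Values are then normalized **per
replicate** (one electroporation day is one experiment) to the mean ratio
of the wildtype construct in that replicate (`normalizeExperiment()`), so
the wildtype mean is exactly 1 in every replicate. Lineage-resolved
analysis uses separate ROIs for the anterior 32 primary and posterior 8
secondary notochord cells; the per-embryo primary/secondary ratio is the
quotient of the two raw reporter/control ratios.

Pairwise construct comparisons (`pairwiseTests()`) use two-sample t
statistics with a single pooled SD across all groups (the default
behavior of R's `pairwise.t.test`, which this reproduces while also
returning the statistic), Benjamini–Hochberg adjustment over the full pair
set, and stars at 0.05/0.01/0.001 on adjusted p-values. Tests are run on
per-embryo normalized ratios pooled across replicates; a per-pair Welch
option exists but is off by default. Treating replicate as a factor would
be a reasonable alternative the package does not currently model.

## Single-cell analysis

Cells are measured as disk-ROI means and split by internal-control
intensity at a strict threshold of 256 (8 in log2 units; the control
histogram is clearly bimodal, so the cut is uncontroversial). Intensities
are floored at 1 before log2 so zeros stay finite while
$\log_2 256 = 8$ exactly. `mosaicismGradedSummary()` reports two numbers
per construct:

* the fraction of control-expressing cells whose reporter also exceeds
  the (same, default 256) reporter threshold — the mosaicism axis;
* the mean log2(reporter/control) among cells above threshold in **both**
  channels — the graded axis.

The conditional mean is computed on doubly-expressing cells: if
reporter-silent cells at baseline were included, a pure increase in
mosaicism would also drag the conditional ratio, and the two axes would no
longer separate. With this definition the signatures are clean: halving
the expressing fraction at unchanged per-cell level moves Δfraction to
−0.5 and leaves the conditional ratio near 0; halving the per-cell level
at unchanged mosaicism leaves the fraction alone and costs one bit.
Because reporter bimodality is imperfect in practice, both the
fixed-threshold fraction and the threshold-free conditional mean are
reported, so conclusions do not hinge on the reporter cut. Regressions of
reporter on control intensity (`expressionRegression()`) are fit on raw
intensities by default, with a log2-space option.

## The synthetic-data generators

The generators are first-class, tested code, and their defaults are the
study conditions:

* **Sequences** (`generateEnhancer()`): 377 bp of i.i.d. background at
  40% GC (a realistic figure for AT-rich tunicate non-coding DNA) with
  planted motif instances, rejection-resampled until no library motif hits
  at the exclusion threshold outside the planted intervals. The planted
  set is therefore the complete ground truth; scanner recall on planted
  consensus sites is 100% by test.
* **Measurements** (`simulateMeasurements()`, `simulateCells()`): per
  embryo, efficiency $E \sim \mathrm{LogNormal}(0, \sigma_E^2)$ shared by
  both channels; per cell, plasmid uptake with probability $m$
  (reporter and control ride the same uptake event by default, since
  co-electroporated plasmids co-segregate — an assumption, switchable);
  expressing cells emit strength × $E$ × LogNormal cell noise, silent
  cells emit a small baseline. Lineages are 32 primary and 8 secondary
  cells; a secondary attenuation factor scales reporter output in the
  posterior 8. LogNormal noise is the natural choice for positive,
  multiplicative intensity variation and is what ratio normalization
  assumes. Defaults $\sigma_E = 1$, $\sigma_{cell} = 1$, $m = 0.6$,
  baseline 10, control strength 1000, reporter scale 2000: these
  magnitudes are not reported by the motivating study, and were chosen
  once so that (i) raw intensities vary severalfold across embryos while
  ratios do not, (ii) the wildtype normalized ratio spreads over roughly
  0.5–2, and (iii) the control channel is bimodal on the log2 scale with
  modes more than 4 log2 units apart, consistent with a 256 threshold.
* **Stacks** (`renderStack()`): Gaussian blobs (default σ = 2 voxels)
  whose integrals equal the per-cell intensities, optional Poisson noise,
  and a matching rectangular notochord ROI. This exercises the
  projection/ROI chain end to end; it does not attempt embryo morphology,
  staining chemistry, or batch effects, so passing tests validate the
  quantitation arithmetic, not image realism.

What the simulations deliberately do not contain: replicate-level batch
effects beyond efficiency, staining artifacts, segmentation error, or
correlations between neighboring cells. Results on synthetic data
demonstrate correctness of the pipeline's arithmetic and its stated
invariances — not biological effect sizes.

## Numerical choices and degenerate inputs

* p-value grid 1/1000 bit; exhaustive enumeration is retained as the test
  oracle for short motifs.
* Zero counts require a positive pseudocount (infinite log-odds
  otherwise); the error is raised at conversion, not scan, time.
* Consensus ties break in A,C,G,T order; design-search ties break by
  summed information content then leftmost position; all searches are
  seed-free and total, so identical inputs give identical plans.
* Polygons enclosing no pixel centers, replicates without wildtype
  embryos, groups with fewer than two values, constant-control
  regressions, and ref-mismatched mutation plans all raise immediate,
  named errors rather than propagating NA.
* Problem sizes in the test suite (motif widths ≤ 8 for enumeration, 50
  synthetic enhancers in the designer sweep, 200 embryos per construct for
  parameter recovery) were chosen as the smallest sizes at which the
  corresponding properties are sharp.

## Known limitations

* Exact reproduction of the motivating study's site counts would require
  its supplementary wildtype sequence and the specific JASPAR 2018 matrix
  versions, neither of which ships with the package; the stylized
  `etsExampleMotif()`/`rbpjExampleMotif()` matrices are clearly labelled
  stand-ins sharing the GGAA core.
* The designer explores transition substitutions inside the hit interval
  only; edits in flanking sequence (which could in principle rescue an
  otherwise infeasible design) are out of scope, as are indels, spacing
  changes and affinity-increasing designs.
* The statistics module implements the pooled-SD pairwise t machinery the
  field uses; mixed models with replicate as a random effect are not
  provided.
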