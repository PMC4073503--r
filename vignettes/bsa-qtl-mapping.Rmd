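---
title: "Mapping fermentation-capacity QTL by bulk segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fermentation-capacity QTL by bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segscan)
```

## The problem and the design

Wine yeasts differ in how well they keep fermenting once assimilable
nitrogen is exhausted. `segscan` implements the genetics workflow used to
map that trait in a haploid F2 cross between two *Saccharomyces cerevisiae*
strains with opposite nitrogen requirements: phenotype every segregant by
its cumulative CO~2~ release at a fixed checkpoint, pool the phenotypic
extremes into two bulks, hybridize pooled DNA to an allele-specific
two-channel array, and scan the genome for markers whose allele frequencies
differ between the bulks. Because the original array data are not needed to
exercise the statistics, the package ships a synthetic-data generator that
reproduces the study design end to end: 6,318 biallelic probe pairs across
the 16 yeast chromosomes, 133 F2 haploid segregants, two bulks of 15, and
replicate probe blocks per array.

## Fermentation phenotyping

Cumulative CO~2~ is obtained from fermenter mass loss,
$\mathrm{CO_2}(t) = (m_0 - m_t)/V$ (`co2FromMass()`). Mass is recorded every
20 min with a weighing precision of 0.01–0.1 g, so tiny apparent mass gains
occur; the cumulative series is clamped to its running maximum, and a dip
at least as large as the precision raises a warning (it indicates a real
disturbance, not jitter). The production rate is estimated by fitting a
second-order polynomial to the trailing window of the last 10 samples and
evaluating its analytic derivative at the window end (`co2Rate()`). The
window is *causal* (anchored at the current point) rather than centered:
the published procedure smooths "the last" measurements, and a causal
window also behaves correctly at the end of a running fermentation. The
first 9 positions carry `NA` rather than zero — zero-filling would fabricate
a low-rate artifact at the start. The checkpoint phenotype is the linearly
interpolated cumulative CO~2~ at 89 h (`phenotypeAt()`), the onset of
stationary phase under the study's nitrogen-limited conditions.

## Population statistics

Broad-sense heritability is computed from the printed formula
$H^2 = 100\,(Var_{seg} - Var_{env})/Var_{seg}$, with $Var_{env}$ the pooled
variance of the parental replicate measurements (`heritability()`). Pooling
is df-weighted, $((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)$ — the natural
reading of "pooled variance" for unequal replicate counts. The estimate is
reported unclipped and flagged when negative, so a user sees estimator
noise instead of a silently truncated 0. Transgressive segregants are those
at least $2\sigma$ beyond the outer parental mean on either side, with
$\sigma$ the pooled parental SD and inclusive boundaries
(`transgression()`). Both statistics are invariant under affine rescaling
of the phenotype, which the test suite checks by property. Bulk selection
(`selectBulks()`) takes the top and bottom $k = 15$ strains by checkpoint
phenotype, breaking ties lexicographically by strain id (low bulk prefers
smaller ids, high bulk larger ones) so the bulks are deterministic and
disjoint.

## The allele-frequency scan

Probe processing follows the two-channel protocol: per block, log~2~
(green/red) ratios are centered to zero mean (`centerLogRatios()`); the
allelic difference at a biallelic locus is the A-allele probe's centered
ratio minus the B-allele probe's (`allelicDifference()`). One affine map —
gain and offset solved from the two parental means — is then applied to all
samples so that the parentA mean is exactly $+1.5$ and the parentB mean
exactly $-1.5$ (`normalizeParental()`). On this scale a pool with A-allele
frequency $f$ sits at $d = 3f - 1.5$ in expectation.

Two testing stages follow:

1. **Informative probes** (`selectParentalProbes()`): per probe, a
   one-tailed Welch two-sample t test over replicate blocks of
   $H_1$: mean $d$(parentA) > mean $d$(parentB), BH-adjusted across probes,
   kept at adjusted $p < 0.05$. The one-tailed direction is fixed by the
   A-minus-B orientation of the allelic difference, so parentA is the
   positive pole by construction. Replicates are the block measurements;
   Welch's correction is used because block variances need not be equal.
2. **Sliding windows** (`windowScan()`): windows of 20 informative probes,
   step 1 (maximally overlapping; the published step is unstated), per
   chromosome in positional order. Each window gets a paired t test across
   its probes of the per-probe difference of bulk means, and p-values are
   BH-adjusted genome-wide (per-chromosome adjustment would change little
   and the genome-wide version is the stricter, simpler choice). A
   chromosome with fewer informative probes than one window contributes a
   single truncated, flagged window.

`callRegions()` retains probes covered by at least one window with adjusted
$p < 0.01$ whose absolute bulk difference also exceeds `parentalFraction`
times the absolute parental difference at that probe, merges retained
probes into regions (bridging gaps of up to 2 non-retained informative
probes, which absorbs isolated noise dropouts), and reports each region's
span, peak probe, minimal window adjusted p and mean bulk difference.
`parentalFraction` defaults to 1/3 with 1/2 available as the stricter
preset: the source analysis states both, and 1/3 is the value tied to its
printed probe count. Enrichment direction (`assignDirection()`) is the sign
of a bulk's mean $d$ over the region: positive means the bulk is enriched
for the parentA origin. A mean of exactly zero is flagged ambiguous. Region
coordinates are 1-based inclusive; BED output converts to 0-based
half-open.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Map** (`yeastMarkerMap()`): 6,318 markers over the 16 chromosomes,
  counts proportional to physical length, uniform spacing, and a uniform
  genetic rate of 0.35 cM/kb — a standard yeast-scale figure, used because
  the source gives no genetic map. Uniform spacing is an assumption; real
  probe spacing is irregular and recombination is non-uniform
  (hotspots/centromeres), so linkage decay around a QTL is smoother here
  than in real data.
* **Meiosis** (`simulateMeiosis()`): crossovers per chromosome are a
  Poisson process in map distance, giving Haldane's
  $r = (1 - e^{-2d})/2$ between markers at distance $d$ Morgans; each
  chromosome's start origin is a fair coin. No interference is modeled.
* **F2 cross** (`makeF2Population()`): F1 gametes of the founder hybrid
  are paired at random (distinct parents) into F2 diploids; one spore per
  diploid is sampled by a second meiosis. Tetrad structure is not retained
  because no downstream analysis uses it.
* **Phenotypes** (`assignPhenotypes()`): additive model,
  $y = \mathrm{baseline} + \sum_l a_l\,[x_l = \mathrm{beneficial}_l] +
  \varepsilon$. The environmental sd is derived from the *realized* genetic
  variance so the expected $H^2$ equals the 0.98 target:
  $\sigma_e^2 = Var_g (1 - H^2)/H^2$. Parental replicates (3 per parent by
  default; the study's replicate count is unstated) get the same sd unless
  `envSdParent` overrides it. An optional pairwise interaction term exists
  because allelic interactions are argued for in this system but never
  quantified; it defaults to empty.
* **Planted architecture** (`defaultQTLModel()`): four equal-effect loci
  (2 g/L each) at the midpoints of the mapped regions — two on chrVII, one
  each on chrXIII and chrXIV — with three beneficial alleles of parent-B
  origin and one of parent-A origin, the reported direction pattern. A
  consequence worth stating plainly: under this 4-locus-only model the
  all-B founder outscores the all-A founder, inverting the real parental
  ranking. That is faithful to the source's own conclusion that undetected
  background loci must explain the parental ranking; modeling such a
  polygenic background would plant extra detectable regions and muddy the
  4-QTL recovery experiments, so it is deliberately omitted.
* **Pool signals** (`simulatePoolSignals()`): expected signal is exactly
  linear in pool allele frequency, $d = 3f - 1.5$, with iid Gaussian probe
  noise (sd 0.1) per replicate block — the simplest model consistent with
  reading extreme hybridization intensities as near-fixation of one
  parental allele. Dye effects, spatial artifacts and probe-specific biases
  are not modeled, so real arrays are noisier and less symmetric than the
  generator.
* **Fermentation curves** (`simulateFermentationCurve()`): a gamma-CDF ramp
  (shape 2, scale 20 h) scaled so the 89-h value equals the phenotype
  exactly; the implied rate rises through growth and declines through
  stationary phase. It is a phenomenological shape for testing the
  phenotyping code, not a kinetic model of fermentation.

All generators are deterministic under a fixed seed; `runPipeline()` fans a
single seed into named per-stage substreams so stages can be rerun
independently.

## What the scan can and cannot deliver at this design size

Power is excellent: with four equal loci at $H^2 = 0.98$, selecting 15 + 15
extremes out of 133 shifts the pool allele frequency at a QTL by roughly
0.8, i.e. a bulk difference near 2.4 on the $\pm 1.5$ scale, and all four
planted regions are recovered in every tested seed.

Specificity is a different matter, and the limitation is structural. At a
marker unlinked to any QTL, each 15-member pool's allele frequency is
$\mathrm{Binomial}(15, 1/2)/15$, so the bulk difference $3(f_H - f_L)$ has
sd ≈ 0.52 and exceeds the one-third-of-parental-difference threshold
($|d_H - d_L| > 1$, about $1.9\sigma$) at roughly 4–5% of probes — in
linkage-correlated clumps, some spanning over a hundred probes. The
within-window paired t test cannot protect against this: pool-composition
noise is nearly constant *within* a window (the same 30 segregants drive
every probe), so a noise clump certifies its own windows. Under the default
conditions the scan therefore calls the 4 true regions plus tens of
spurious ones per genome (about 50–80 at fraction 1/3; 11–18 at the 1/2
preset). This mirrors the source analysis itself, which found 23
significant regions and restricted attention — by its own description,
arbitrarily — to the four with the largest bulk differences. The honest
summary: with bulks of 15, the parental-fraction threshold ranks regions
but does not control false positives; trustworthy specificity needs larger
bulks, replicate bulk pairs, or a test that models pool sampling noise
(e.g. G'-type smoothed statistics used in modern sequencing-based BSA).
The package implements the published procedure as specified and exposes
`parentalFraction` so users can reproduce either published threshold.

## Numerical choices and degenerate inputs

* Normalization requires distinct raw parental means; equal means raise a
  degenerate-normalization error rather than producing infinities.
* Zero-variance probes in the parental test get $t = \pm\infty$ by the
  sign of the mean difference (p of 0 or 1), keeping BH well defined.
* A window with zero spread and zero mean gets $t = 0$, $p = 1$.
* `co2Rate()` centers each window's time at its last point before solving
  the least-squares system, which keeps the design matrix well conditioned
  and makes the derivative the linear coefficient directly.
* Heritability requires at least 2 values per group and positive segregant
  variance; violations raise errors rather than NaNs.
* Region merging counts gaps in informative-probe order, not bp, so a
  sparse chromosome cannot bridge huge physical distances through a
  2-probe gap.

## Problem sizes used by the test suite

Unit tests run on compact two-chromosome maps (tens of markers) with
directly constructed pool-frequency tables, so every statistical operation
is checked against hand-computed or brute-force oracles in milliseconds.
The calibration and recovery experiments run at the full study design
(6,318 markers, 133 segregants, 20 seeds), which completes in about a
minute and a half; heritability calibration in the unit suite uses a
1,000-marker map, since the phenotype model only touches the markers
nearest the four loci.
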