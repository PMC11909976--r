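---
title: "Mutational constraint for short open reading frames: models and methods"
author: "sorfConstraint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational constraint for short open reading frames: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfConstraint)
```

## The problem

Short open reading frames (sORFs) are non-canonical reading frames of fewer
than 100 codons — upstream/downstream ORFs in UTRs (uORF/dORF), ORFs
overlapping canonical coding sequence (uoORF/doORF/intORF), and ORFs on
lncRNAs. Whether a given sORF encodes a functional microprotein is usually
unknown. One line of evidence is *mutational constraint*: depletion of
standing variation in a large population cohort relative to what a neutral
mutational model predicts. A region that tolerates fewer missense variants
than expected, specifically in *its own* reading frame, behaves like coding
sequence under purifying selection.

This package implements that workflow end to end: it reads sORF definitions
(BED12 with blocks), classifies every possible single-nucleotide variant in
the sORF frame, computes expected variant counts from a
trinucleotide-context, methylation-aware mutation-rate model, counts
observed variants from a population variant table under quality filters,
and summarises constraint as the observed/expected upper-bound fraction
(OEUF) for three classes: all SNVs (SNVOEUF), missense (MOEUF), and
loss-of-function, i.e. start-loss + stop-loss + stop-gain (LOEUF).
Downstream comparisons — decile cut-offs, the frame-respect flag, regional
UTR constraint, score-track matching, and rank statistics — are included,
as is a synthetic-data generator that emulates every input so the whole
chain is testable without any external download.

## Coordinate conventions

All internal interval objects are `GRanges`/`GRangesList` (1-based,
closed), the native Bioconductor convention. Conversions happen only at
format boundaries: BED input/output through `rtracklayer` (0-based
half-open on disk), GTF output 1-based inclusive, VCF positions 1-based.
Keeping a single in-memory convention, delegated to containers that
enforce it, is what prevents off-by-one drift.

## Sequence model: spliced codons, genomic contexts

`extractCodingSequence()` concatenates the block sequences (reverse
complement for minus-strand sORFs) into a translation-ordered coding
sequence, and attaches to each base its *genomic* context triplet — the
base with its two immediate genomic neighbours, oriented to the coding
strand. Two choices here were genuinely open and are fixed as follows:

* **Contexts are genomic (pre-splicing), codons are spliced.** The
  mutational mechanism acts on genomic DNA, so at a splice junction the
  context of an exon-edge base uses the intronic neighbour, not the next
  exon's base; translation, in contrast, acts on the spliced sequence.
  A dedicated test constructs a junction where the two choices differ.
* **Non-ATG first codons are accepted but flagged** (`startIsATG`); the
  consensus sORF catalogues are ATG-initiated, so the flag should be rare
  on real data, but synthetic or user data may violate it.

Codons touching an ambiguous reference base (N) are excluded from
enumeration; a flank-N poisons only the affected base's context.

## Consequence classification

`classifyChange()` classifies a single-base codon change by the standard
nuclear genetic code with priority
`start_loss > stop_loss > stop_gain > (synonymous | missense)`:

* any amino-acid-changing substitution in the first codon is `start_loss`
  (a synonymous change in a non-ATG start stays synonymous — ATG has no
  synonymous changes, so this only matters for flagged starts);
* a change in the terminal codon producing a non-stop codon is
  `stop_loss`; stop-to-stop changes are counted as `synonymous` (this
  choice is isolated in one function and documented, since annotators
  differ);
* elsewhere, stop-creating changes are `stop_gain`, and the rest split by
  amino-acid identity.

The suite checks all 64 codons x 9 changes against an independent
translate-and-compare oracle built on `Biostrings::translate()`. There is
no splice class in this engine; when externally annotated variants are
imported, splice-only records should be excluded upstream (the engine never
produces them natively).

## Mutation model and expected counts

Every non-excluded codon contributes exactly 9 possible variants (3 bases x
3 alternates). Each possible variant carries a mutation rate looked up by
(context triplet, alternate allele, methylation bin). Lookups are
strand-symmetric: published rate tables are strand-collapsed, so a context
missing from the table is retried as its reverse complement with the
complementary alternate.

Methylation is summarised per position as the mean fraction across
epigenomes (37 in the emulated input), binned into 16 equal-width bins on
[0, 1] (left-closed, right-open, last bin closed: 0.5 is bin 8, 1.0 is bin
15). Bins are applied only where the genomic context contains a CpG
dinucleotide; elsewhere bin 0 is forced (configurable off), since
methylation-dependent rates are a CpG phenomenon.

Possible variants are excluded — mirroring the observed-side filters — when
their site carries a low-quality variant call, when the matching observed
allele is common (allele frequency >= 0.1%), or when site depth is below 1.
The same single per-site depth value serves both the observed-side filter
and the possible-side filter; the upstream cohort summaries this emulates
publish one depth statistic per site.

### Calibration: from rate sums to expected counts

Two calibrations are provided:

* `fitCalibration()` — a zero-intercept least-squares factor `k` fit on
  per-element (observed synonymous count, synonymous rate sum) pairs, with
  `E = k * sum(mu)`. This is the simplest defensible mapping and is exact
  when the cohort is small enough that the expected number of segregating
  sites is linear in the mutation rate.
* `fitProportionCalibration()` — a nonparametric proportion-observed curve:
  per distinct mutation rate, the fraction of synonymous possible variants
  observed as (rare, passing) segregating sites; expected counts are sums
  of those fractions. This is the default in `simulateSorfStudy()`.

The second exists because the first is *structurally* mis-calibrated at
realistic cohort sizes. Methylated CpG transitions mutate an order of
magnitude faster than other sites and carry roughly half of the total rate
mass even in a CpG-depleted genome; at cohort scales large enough to power
short elements (>= 10 expected SNVs over ~50 codons), those sites saturate
— the number of *unique* segregating sites grows like `1 - exp(-s*mu)`, not
linearly. A single global factor fit on synonymous sites absorbs the
synonymous mixture of saturation and then over-predicts classes with *less*
CpG exposure: start- and stop-codon changes involve no CpG transitions at
all, and their observed/expected ratios come out 10–20% high under the
linear factor. Calibrating the observed proportion per rate — in the spirit
of the published constraint pipelines this workflow adapts, which calibrate
per context and methylation level — removes the bias (verified in the
neutral-recovery tests). The linear factor remains available, reported, and
appropriate for small cohorts.

## Observed counts

`filterObserved()` keeps unique variants with allele frequency strictly
below 0.1%, passing filters, and per-site depth >= 1 (boundaries: AF equal
to the threshold is dropped, depth equal to 1 is kept — both taken verbatim
from the workflow's stated rules, which agree at the boundary).
`countObserved()` counts unique variants per element and class, and can be
restricted to the retained possible-variant site space so that the observed
and expected sides see identical sites; the pipeline-level wrappers always
do this, since excluding a site from the expectation while counting its
sibling alleles in the observation would bias ratios upward by a few
percent.

## The Poisson grid and the OEUF

For an element with observed count `k` and expected count `lambda'`, the
Poisson pmf `G(X = k) = lambda^k e^(-lambda) / k!` is evaluated at
`lambda = x * lambda'` for the ratio grid `x = 0, 0.001, ..., 2`; the pmf
sequence is cumulated and normalised to end at 1, and the bounds are the
smallest grid ratios whose normalised cumulative value reaches 0.05 and
0.95. The upper bound is the OEUF — a deliberately conservative, one-sided
summary: small expected counts widen the interval and push the OEUF up,
so under-powered elements look unconstrained rather than constrained.

Numerical notes, all covered by tests against an independently coded grid
oracle and a closed form at `k = 0`:

* the grid caps OEUF values at 2.0 by construction; elements whose
  cumulative never reaches 0.95 below 2.0 report 2.0;
* `expected = 0` is degenerate (uniform grid) and reported as not
  computable rather than silently zero;
* the source text describing this procedure states a step of 0.001 over
  [0, 2] in prose but a formula implying 0.0001 over [0, 0.2]; the prose
  wins here (the step is configurable), and at `lambda' = 20` the
  resulting 90% interval covers the truth in ~90.6% of simulated
  replicates;
* elements are *powered* when the expected count of the relevant class is
  at least 10; under-powered results are kept but flagged, and excluded
  from decile assignment and frame-respect tallies.

## Deciles, frame respect, regional UTR constraint

`decileCutoff()` sorts values ascending into 10 equal-count bins (bin of
sorted position `j` is `ceiling(10j/n)`; ties broken by a stable sort on
value then element id) and returns the maximum of the lowest bin — the
constraint cut-off. Equal-count rather than equal-width bins because the
procedure is a decile split of a skewed distribution.

`frameRespectFlag()` is the workflow's overlap heuristic: an element with
MOEUF strictly below SNVOEUF is depleted of missense variation *beyond*
its general SNV depletion, which is the signature of constraint acting in
the element's own reading frame rather than through an overlapping
feature. It is only evaluated when both results are powered.

`regionalUtrConstraint()` marks a gene whose UTRs occupy deciles separated
by at least two others (index difference >= 3), after dropping UTRs that
are under-powered or shorter than a minimum length (default 800 bases in
the pipeline configuration, the mean UTR length in the emulated dataset —
OEUF correlates strongly with element length, so length filtering guards
against calling a length artefact "regional constraint").

## Score-track matching

`matchElement()` averages interval scores (e.g. per-kilobase constraint
z-scores published at 1 kb resolution, sliding by 100 bp) over a genomic
element: by default the unweighted mean of all track windows fully
contained in the element, falling back to the mean of the two closest
windows (one per side on distance ties) when none is contained — short
elements rarely contain a 1 kb window. An any-overlap mode with an
optional uniqueness requirement handles non-overlapping track variants.
Window overlap lengths do not weight the mean; the emulated upstream
procedure averages plainly. `gnocchiConstrained()` applies the published
cut-off of 4 (boundary inclusive) marking the most constrained percentile.
`matchBlocks()` averages per-position scores (e.g. conservation scores)
over coding blocks, reporting the covered fraction.

## Rank statistics

`varghaDelaneyA()` (probability that a value from group one exceeds one
from group two, ties counted half, computed exactly via mid-ranks),
`meanRanks()` (pooled average ranks and the U statistic), and
`runComparisons()` which orchestrates the classical tests around them:
two-sample Kolmogorov–Smirnov, Mann–Whitney U (with mean ranks and A),
Wilcoxon signed-rank for paired designs, Kendall's tau (tau-b, the
tie-corrected variant — constraint tables are tie-rich). p-values below
0.001 are rendered as "<0.001" in labels, with raw values kept in the
machine columns. Overlapping sORF classes (intORF, uoORF, doORF) are
excluded from unpaired tests by default: their constraint values are not
independent of the canonical coding regions they overlap.

## The synthetic-data generator

`simulateSorfStudy()` generates every input the workflow reads and runs
the full chain on it. What it emulates, and what it deliberately does not:

* **Reference** (`generateReference()`): i.i.d. bases at a configured GC
  (default 0.42), then CpG depletion to 25% of random expectation by
  deamination-style C-to-T replacement — reproducing the one compositional
  feature the mutation model is sensitive to. No repeats, isochores, or
  chromosome structure.
* **sORFs** (`plantSorfs()`): ATG-initiated, internally stop-free frames of
  20–100 codons in 1–3 blocks, planted non-overlapping on both strands;
  overlap classes are embedded in recorded canonical-gene intervals. The
  default study holds 600 sORFs in the catalogue's class proportions
  (uORF-heavy), a ~1/12-scale version of the consensus catalogue.
* **Variants** (`simulateVariants()`): each possible variant segregates
  with probability `1 - exp(-cohortScale * mu * selection[class])` — the
  probability that a Poisson number of mutation events is at least one —
  with per-class selection factors in (0, 1]. Site-level nuisance is
  planted at configured rates: 2% common alleles (AF >= 0.1%), 2% non-PASS
  calls (whose positions become low-quality sites), 1% of positions with
  depth below 1. There are no genotypes, no linkage, no demography: the
  workflow consumes site-level summaries only, so none of that structure
  is needed to exercise it.
* **Tracks** (`generateTracks()`): 37 methylation tracks with
  CpG-localised, bimodal (mostly-methylated) signal and Beta observation
  noise; a sliding score track (1000/100 by default) with standard-normal
  or constant scores.

`cohortScale` defaults to 6e6, chosen so that a median-length sORF has
about 15 expected SNVs and ~80% of sORFs are powered for missense — the
powered proportions the real cohorts show for this element class. The toy
rate table uses a 4e-9 transversion rate, transitions 3x, and a CpG
deamination transition multiplier linear in the methylation bin reaching
10x at full methylation, reproducing the qualitative rate structure
(CpG-transition dominance, methylation dependence) without claiming the
published values.

Passing tests on these data demonstrate that the *inference machinery*
recovers what the generator planted (neutral ratios near 1, ~90% interval
coverage, selection detected as MOEUF < SNVOEUF); they cannot demonstrate
robustness to real-data pathologies the generator omits — mis-annotated
ORFs, segmental duplications, population stratification of allele
frequencies, or rate-model misspecification.

## Problem sizes and determinism

The test suite runs the neutral-recovery check on 3000 planted sORFs
(~2 Mb genome, ~1.7 M possible variants, about a minute) and the selection
check on the 600-sORF default; the acceptance script uses 1500 sORFs for
the neutral cohort. These sizes were chosen by a pre-run power analysis so
that the loss-of-function aggregate ratio — the noisiest reported class,
driven by ~1–2 observed LoF variants per element — has a sampling SD
under 2%, comfortably inside the 5% recovery band. Every stochastic stage
seeds deterministically from the configuration seed (stages use seed,
seed+1, seed+2, seed+3), so reruns are byte-identical; the command-line
stages additionally stamp outputs with a config fingerprint.

## Known limitations

* LOEUF at desk scale is almost always under-powered — as it is at real
  cohort scale for elements this short; the package reports it flagged
  rather than hiding it.
* The proportion-observed calibration needs enough synonymous sites per
  rate group (default minimum 50); tiny studies should use the linear
  factor.
* The consequence engine is SNV-only by design: no indels, no MNVs, no
  splice classes.
* `runComparisons()` applies no multiple-testing correction, matching the
  descriptive usage it supports; treat its p-values accordingly.
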