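---
title: "Blank-informed tag-jump filtering and downstream diversity: methods"
author: "jumpsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blank-informed tag-jump filtering and downstream diversity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpsieve)
```

## The problem

In multiplexed amplicon sequencing, index (tag) combinations identify which
sample each read came from. A small fraction of reads is systematically
mis-assigned — *tag jumping* or *index hopping* — so an ASV genuinely present
in one sample leaks false-positive observations into others. A separate
error class produces spurious low-read ASVs seen in a single sample only.
Both blur diversity patterns: false positives inflate richness and erode
between-site differences.

`jumpsieve` implements a decontamination strategy that calibrates its
thresholds on *blank samples*: index combinations that were never used in
the experiment. Any read assigned to a blank is a known error, so the
distribution of blank observations tells us what errors look like in this
particular sequencing run — no fixed, arbitrary cutoff is imported from
elsewhere.

## Per-observation statistics

An *observation* is one (ASV, sample) cell with a positive read count.
For each observation the package computes

* `readprop` — the observation's share of its ASV's total reads,
  `reads / total reads of that ASV`;
* `exprop` — the share expected if the ASV's reads were spread evenly over
  its observations, `1 / (number of observations of that ASV)`;
* `norm` — the relative divergence `(readprop − exprop) / exprop`,
  bounded below by −1.

A hopped packet of reads typically holds a tiny fraction of an abundant
ASV's reads: small `readprop`, `norm` close to −1. An ASV found in exactly
one sample has `readprop = 1` and `norm = 0`.

Statistics are computed **once on the raw table** (blank reads included in
the denominators), because the thresholds themselves are derived from blank
observations of that same table. Two alternative readings are exposed as
switches: `recomputeStatsAfterFilter1` recomputes the statistics after the
first filter, and the `readprop` denominator question has no independent
switch because dropping blank reads before the derivation would remove the
very signal the thresholds are calibrated on.

## Threshold derivation and the two filters

All thresholds come from Tukey's boxplot rule: hinges by the
five-number-summary convention (hinge depth `(⌊(n+1)/2⌋+1)/2`, averaging
when fractional), upper fence `upper hinge + 1.5 × (upper hinge − lower
hinge)`, and *outliers* defined as values strictly above the fence.
Fences are one-sided: for read counts only the high side is meaningful,
and both filter-2 thresholds are minima of high-side outlier sets.

1. **Sequencing-error filter.** Observations whose ASV occurs in exactly
   one sample, that sample being a blank, cannot be tag jumps — they are
   sequencing errors. Their read counts are split by the fence; the
   threshold `tReads` is the **maximum of the body** (keeping the outliers
   in would eliminate far too much downstream). All observations with
   `reads ≤ tReads` are then removed — first in the blanks, later in the
   real samples. The comparison is inclusive because the threshold is the
   largest *known error*; a strict reading (`filter1Strict = TRUE`) is
   available.
2. **Tag-jump filter.** From the blank observations that survive filter 1,
   the high-side outliers of the `readprop` column and of the `norm`
   column are taken independently; each threshold is the **minimum of its
   outlier set** (`tReadprop`, `tNorm`). An observation in a real sample
   is then retained iff it passes *at least one* threshold:
   `readprop > tReadprop` **or** `norm > tNorm` (strict, disjunctive).
   Both outlier sets are taken from the same post-filter-1 blank pool;
   neither is conditioned on the other.

The full pipeline (`runBlankFilter()`) runs: statistics → derive `tReads`
→ filter 1 on blanks → derive (`tReadprop`, `tNorm`) → filter 1 on real
samples → filter 2 on real samples → drop the blank samples. Every step
logs its observation and read counts, and the returned
`FilterThresholds` object carries full provenance (the exact value
vectors, hinges, fences and splits); `replayThresholds()` must reproduce
the cutoffs bit-exactly.

Degenerate inputs follow explicit contracts rather than silent defaults:
no blanks, fewer than `minBlankErrors` (default 5) backing observations,
or an empty outlier set each raise a precondition error that advises
supplying manual thresholds — a data-driven rule is undefined without
data. Separately, ASVs can be dropped when their percent identity to the
target clade falls strictly below `minIdentity` (default 84, the
empirical clade boundary for this COI fragment).

## OTU clustering at the barcoding gap

ASVs are grouped into OTUs by agglomerative **complete-linkage**
clustering of pairwise distances, cut so that no cluster contains a pair
farther apart than `cutoff` (default 0.03 — the 3% barcoding gap for the
marker). Complete linkage makes the cut semantics exact: the merge height
of a cluster *is* its maximum pairwise distance.

Distances are uncorrected p-distances with pairwise deletion (columns with
a gap or ambiguity in either sequence are skipped); a Jukes–Cantor option
exists. Pairs with no comparable columns are an error, not a zero.

Clustering libraries usually leave equal-distance merge order unspecified;
here ties are broken by the lexicographic order of the candidate clusters'
smallest member labels, so the partition is reproducible and invariant to
input order. OTU ids are named after the lexicographically smallest
member. Each OTU gets one representative — the member with the most reads,
ties to the smallest id — and the ASV tree is pruned to representatives
(`collapseTree()`), suppressing degree-2 nodes with branch lengths summed,
which preserves patristic distances between survivors.

## Alpha diversity, depth correction, beta partition

* **Richness** is the count of OTUs with reads > 0 per sample.
* **Faith's PD** is the branch-length sum of the minimal subtree
  connecting a sample's OTUs. The root path is included by default
  (matching the classic implementation), so a single-OTU sample has its
  root-path length; `includeRoot = FALSE` roots the subtree at the MRCA
  instead. Empty samples have PD 0.
* **Depth correction**: diversity is regressed on sequencing depth by
  OLS and the residuals taken as depth-corrected diversity — a positive
  residual means more diversity than the sample's depth predicts. Scaled
  (z-scored) residuals are reported alongside raw ones; residuals that
  are zero up to round-off are not inflated into unit-variance noise
  (tolerance `1e-10 × max(|diversity|, 1)`). Constant depths leave the
  slope undefined: an error by default, mean-centring on request.
* **Beta diversity** uses the Baselga partition of Sørensen
  dissimilarity into turnover (Simpson dissimilarity, β~SIM~) and
  nestedness-resultant (β~SNE~ = β~SOR~ − β~SIM~) components, pairwise
  and multi-site, on presence–absence. The multi-site form uses the
  standard pair sums `Σ min(b_ij, b_ji)` and `Σ max(b_ij, b_ji)` with
  `core = Σ S_i − S_T`. Within-group variability is described by
  resampling `nSites` samples (default 20) without replacement `nIter`
  times (default 1000) and recording the multi-site triple per draw;
  sampling *with* replacement would duplicate sites and distort the
  multi-site sums. A `meanPairwise` switch records the mean of pairwise
  triples instead, covering the alternative reading of a per-draw
  "average". Exclusive-OTU (Venn region) counts are enumerated per group
  combination and always sum to the pooled richness.

## The synthetic benchmark

The simulator provides ground truth that no real run can: every
observation is labelled `genuine`, `tagjump` or `seqerror`, so any filter
can be scored for sensitivity and specificity (`scoreFilter()`).

The reference scenario: 4 sites × 6 samples plus 4 blanks, 50 species ×
3 ASVs (150 genuine ASVs), mean depth 5×10⁴ reads per sample, hop
probability 0.02 per read, 50 spurious error ASVs, seed 42. Free
parameters were fixed once at field-realistic values: lognormal species
abundances with log-sd 1.5 (metabarcoding abundances span orders of
magnitude), site occupancy 0.6 (communities overlap but differ), and
shifted-geometric error reads with p = 0.3 (most errors are one or two
reads; a heavy tail gives the outlier-removal step real work).

Generative model, in order:

1. **Community**: species occupy sites independently with the occupancy
   probability (a `nestedSites` switch makes poorer sites strict subsets
   of richer ones instead); cell counts are Poisson around lognormal
   abundance × depth. Totals therefore vary around the mean depth —
   counts are drawn per cell, not multinomially per sample.
2. **Tag jumps**: each read hops independently with probability `pJump`
   to a uniformly chosen other index combination, used or blank. Reads
   are conserved exactly; destination cells that were empty become
   `tagjump` observations.
3. **Sequencing errors**: novel single-observation ASVs with
   `1 + Geometric(p)` reads. The blank/used split of their destinations
   is fixed at its expectation (uniform within each stratum): with ~7
   expected blank errors, a binomial draw would leave roughly one run in
   ten below the five-observation derivation guard, making the benchmark
   unusable at those seeds for no informative reason.
4. **Sequences**: an alignment whose intra/inter-species separation is
   guaranteed and verified — species codes over shared diagnostic
   positions are resampled until every pair differs by at least
   `dBetween × length`, and within-species variation is confined to
   non-diagnostic positions so it can never erode that floor. Error ASVs
   are one substitution away from a random genuine parent and grafted
   onto the tree as near-zero-length sisters, so clustering and PD stay
   defined for any error that survives filtering.

What the simulator does **not** emulate: pair-structured hopping (real
index hopping depends on which tags share a lane; the filter is
destination-agnostic, so uniform hopping is the minimal sufficient
model), chimeras, PCR bias, read-level errors, and the extreme sparsity
of real protist tables — within-site beta diversity is accordingly
milder than in field data. Passing the benchmark therefore shows the
machinery is correct and well-calibrated on its stated error model, not
that the thresholds transfer to any particular real run — which is the
point of deriving them per run.

## Determinism and problem sizes

Every stochastic routine takes an explicit seed, and the pipeline writes
byte-identical artifacts for identical configuration and seed (stage
wall-clock times live only in the in-memory report for this reason).
The test suite exercises the reference scenario end-to-end plus
property checks at sizes chosen for sharp verdicts at interactive run
times: 1000 random vectors against a brute-force hinge oracle, 1000
random presence–absence matrices for the beta identities (additivity to
1e-12), exhaustive partition enumeration up to 8 ASVs, 100 random trees
for PD monotonicity, and 50 Monte-Carlo seeds for the hop-rate
expectation (3 standard errors).

## Known limitations

* The filter is threshold-based and destination-agnostic; it does not
  model which index pairs exchange reads.
* Filter-2 thresholds require outliers among blank observations; runs
  with too little blank signal need manual thresholds (the error message
  says so).
* The representative-ASV choice (abundance-based) and the p-distance
  model are documented defaults, configurable where the underlying
  convention is genuinely unspecified.
* GLMMs, PERMANOVA, NMDS and significance testing are out of scope; the
  outputs are tables ready for those tools.
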