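---
title: "Detecting piRNA signatures in oxidized small-RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting piRNA signatures in oxidized small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnasig)
```

## The problem

PIWI-interacting RNAs (piRNAs) are 24–32 nt small RNAs, mostly antisense to
transposable elements (TEs), that carry three sequence-level hallmarks of
their biogenesis:

* **1U / 10A ping-pong bias.** Reciprocal cleavage between sense and
  antisense piRNAs with a 10-nt 5′ overlap enriches uridine at position 1
  of TE-antisense reads and adenine at position 10 of TE-sense reads.
* **Phasing.** Processive, head-to-tail piRNA production leaves a uridine
  bias at the genomic base immediately 3′ of a piRNA's end (a downstream-U
  frequency of roughly 50% is typical of phased populations, against a 25%
  background).
* **2′-O-methylation.** Mature piRNA and siRNA 3′ ends are
  2′-O-methylated, which protects them from sodium periodate oxidation;
  building libraries from oxidized RNA therefore enriches piRNA/siRNA
  species over unmethylated RNA.

`pirnasig` implements the complete desk-scale analysis that turns a raw
small-RNA FASTQ into these statistics — adapter/UMI preprocessing,
tiered mismatch-bounded mapping, signature computation, masked genome-tile
quantification of piRNA-cluster abundance, and length-normalized TE mRNA
abundance — together with a simulator that generates libraries with
exactly the generative structure the analysis detects, so every stage can
be validated against known ground truth.

## Pipeline model and conventions

Coordinates are 0-based and half-open everywhere (BED-native); sequences
are stored as DNA, with U in reports being a display alias for T; `N`
never matches any base, including `N`. The stages are:

1. **Preprocess.** Reads are truncated at the leftmost exact occurrence of
   the 3′ adapter (`AGATCGGAAGAGCACACGTCT` by default; full adapter
   anywhere, or an adapter prefix of ≥ 6 nt anchored at the read end).
   The 4 randomized nucleotides at either end of the insert are removed,
   and inserts of 18–40 nt (inclusive) are retained. No quality filter is
   applied. Discard categories partition the input exactly.
2. **Infrastructural annotation.** Inserts are mapped with ≤ 1 mismatch to
   rRNA/snRNA/snoRNA/miRNA/tRNA and hairpin-RNA (hpRNA) sequences. The
   hpRNA-mapping read count is the normalization denominator ("per
   million hpRNA reads") for size distributions and tiles; endogenous
   hpRNA-derived siRNAs survive oxidation, which makes them a stable
   internal scale. Annotation never removes reads from later stages.
3. **Genome mapping.** ≤ 1 mismatch, both strands, all-best-strata: only
   placements tied at the per-read minimal mismatch count are reported.
   Reads with exactly one best placement are the "unique mappers" used in
   tile analysis. Each read carries total weight 1, split evenly over its
   reported placements, so weighted counts conserve read totals.
4. **TE mapping.** The same mapper against the TE consensus library with
   ≤ 3 mismatches. The stored consensus is the element's sense strand, so
   plus-strand alignments are sense and minus-strand antisense; a read
   placed in both orientations (a reverse-complement palindrome)
   contributes half weight to each. Genome and TE mapping are independent
   (they do not compete for reads).
5. **Signatures.** Size distributions per orientation; 11-position
   nucleotide-frequency windows anchored on antisense position 1 and sense
   position 10 (reads > 22 nt only); ping-pong z-scores; downstream-U
   frequency; TE-mapping fraction.
6. **Tiles.** tRNA/snRNA/snoRNA features padded ± 100 nt plus the
   aubergine-like locus form an exclusion mask (merged intervals; any ≥
   1-nt overlap removes an alignment). Surviving unique mappers are
   assigned to fixed-width tiles (default 1,000 nt) by their 5′ end, then
   aggregated to piRNA-cluster abundances by tile midpoint and expressed
   relative to a reference library.
7. **TE expression.** For transcript count tables,
   `rate = count / length` and
   `abundance = rate × 10⁶ / Σ rate` over host and TE transcripts
   together; per-TE log2 ratios between libraries use a pseudo-abundance
   (default 1) to guard zeros.

### The z-score convention, and its ceiling

The ping-pong z-score is the deviation of the anchor-position frequency
from the mean over the 11 window positions, divided by the *population*
standard deviation (divisor n) of those 11 values. The window includes the
anchor. Two consequences are worth stating explicitly because they shape
what values the statistic can take:

* a window in which 10 positions share one value and the anchor takes any
  other value gives exactly |z| = √10 ≈ 3.1623 (this closed form is
  asserted in the tests for arbitrary baseline and outlier values);
* √(n−1) = √10 is the **attainable maximum** of any population z-score
  within an 11-value sample, so a strongly biased library *saturates*
  near 3.16 rather than growing without bound.

A consequence of the ceiling: once the 1U bias is strong, z₁U no longer
responds to changes elsewhere in the biogenesis (for example the
ping-pong pairing rate) — its residual variation across conditions is
sampling noise at the fifth decimal. z₁₀A, in contrast, rises cleanly
from noise level to the cap as the ping-pong fraction increases (≈ 0.65
at fraction 0 to ≈ 3.16 at fraction 1 under the test conditions). A
degenerate window (zero SD) returns z = 0 with a flag rather than an
error, since tiny toy inputs can produce constant windows.

Window geometry: the anchor sits at the center (index 5 of 0..10).
Positions inside the read are read from the read sequence; positions
upstream of the read's 5′ end come from the alignment target on the read
strand, which is the aligned-window convention sequence-logo tools use.
Alignments whose window would run past the target end are dropped and
counted.

## What the simulator emulates

`build_toy_reference()` generates a toy genome (default 3 × 50 kb), a TE
consensus library (6 × 3 kb), two 8-kb piRNA clusters tiled with TE
consensus fragments inserted predominantly antisense, diverged dispersed
TE insertions, and at least one locus of every annotation class.
`simulate_small_rna()` then draws reads whose statistical structure is the
one the analysis measures:

* piRNA 5′ ends are placed inside cluster TE fragments such that the 5′
  base is U with probability `u1_bias` (default 0.9), and insert lengths
  (23–32 nt) are chosen so the next genomic base on the read strand is U
  with probability `phasing_downstream_u` (default 0.5), by rejection
  sampling of (position, length) pairs;
* with probability `pingpong_fraction` an antisense piRNA receives a
  sense partner on the opposite genome strand whose 5′ end lies 10 nt
  into the mate, making the partner's 10th base the complement of the
  mate's 1st (10A when the mate starts with U). Partner lengths are drawn
  independently; only the 5′ geometry is constrained. The phasing rule
  also sets partner 3′ ends — without it, partners would dilute the
  measured downstream-U frequency below its configured value;
* hpRNA-derived siRNAs are 21 nt, miRNAs 22 nt from fixed mature
  positions, degradation fragments uniform 18–40 nt from random loci;
* methylation is drawn per class (piRNA/siRNA ≈ 1, backgrounds ≈ 0) and
  `apply_oxidation()` retains methylated reads with probability 1,
  unmethylated ones with probability 0.02;
* `render_fastq()` wraps each insert as `UMI(4) + insert + UMI(4) +
  adapter`, padded with random bases to 75 cycles, constant quality, with
  a sidecar truth table carrying class, placement, methylation, partner
  linkage and adapter presence.

### Design choices, and what they are for

* **Uniform base composition (25% each).** The "no bias" control sets
  `u1_bias = 0.25`, which is only a genuine null if the background 5′-U
  rate is 0.25. Biases are therefore imposed by rejection sampling rather
  than by skewing cluster composition; a composition skew would
  manufacture spurious z-scores in the unbiased control, because the
  anchor frequency is pinned by the selection rule while the rest of the
  window follows composition.
* **Disjoint consensus regions per fragment; diverged insertions.**
  Cluster fragments are carved from non-overlapping regions of the
  consensus elements, and dispersed insertions are 20% diverged, so
  piRNA-sized reads map the genome uniquely at ≤ 1 mismatch. This keeps
  the phasing measurement undiluted (a multi-mapped read would average
  its true downstream base with a random one) and makes the tile analysis
  attribute cluster reads to their source cluster.
* **Class fractions** default to piRNA 0.5, siRNA 0.2, miRNA 0.1,
  degradation 0.2. No per-class abundances are published for the tissue
  this models, so these are free parameters chosen once to give a
  piRNA-rich oxidized library with a ≥ 30% unmethylated background — the
  regime in which the oxidation contrast (enrichment of piRNA-sized
  TE-antisense reads after oxidation) is visible.
* **`n_reads` counts primary reads;** ping-pong partners are emitted in
  addition and linked via `partner_id`. Parameter-recovery statistics
  (for example the u1 bias) are measured over primary reads, because a
  partner's 5′ base is fixed by the overlap geometry, not by `u1_bias`.
* **UMIs are uniform random with no whitelist** and no deduplication, and
  quality strings are constant: the modelled protocol applies neither a
  UMI collapse nor a small-RNA quality filter.

What the simulator does **not** model: sequencing errors, PCR
duplication, ligation bias, and gel size-selection efficiency curves. A
green test suite therefore shows that the analysis recovers the
generative parameters of an idealized library; it does not certify
behaviour under error-containing real data, where the mismatch allowances
(1 genome / 3 TE) absorb sequencing errors in a way the simulation never
exercises.

## Numerical conventions and degenerate inputs

* Zero hpRNA reads: per-million columns become `NA`; raw counts are kept.
* Zero usable alignments: frequency matrices carry an `empty` flag;
  downstream-U frequency is `NA` with the weight that produced it.
* A piRNA cluster shorter than a tile may cover no tile midpoint; its
  abundance is 0 with a warning.
* A zero reference-cluster abundance flags the ratio `NA` rather than
  dividing by zero; TE expression ratios use the configured
  pseudo-abundance.
* Ties in mapping are never broken: all-best-strata reports *every*
  minimal-mismatch placement and downstream weights split evenly.
* "Longer than 22 nt" is implemented as length ≥ 23; the upper bound is
  the global 18–40 selection. Size selection is applied once to the clean
  read set used by every downstream stage.

## Problem sizes used in validation

The test-suite simulations use the default toy reference and libraries of
8,000–50,000 primary reads: 50,000 for the phasing-recovery and
z-score-response checks (binomial noise on a frequency at n ≈ 35,000
usable alignments is ± 0.005, comfortably inside the ± 0.02 recovery
band), 20,000 for the TE-fraction and oxidation-contrast checks, 10,000
for u1 recovery, and 200 random reads × 3 references × mismatch settings
{0, 1, 3} for exhaustive agreement between the mapper and an independent
brute-force scanner. The full suite runs in under a minute on one CPU.

## Known limitations

* The toy TE library is a stand-in: no curated transposon sequence set is
  reproduced, and no real genome coordinates (42AB, 38C, flamenco) exist
  here.
* The mapper is exhaustive and mismatch-only (no indels, no
  quality-aware scoring); it is built for toy-scale references, not
  genome-scale performance.
* The classic 5′-overlap ping-pong histogram (z over overlaps 1–20) is
  not implemented; the positional-frequency z-score is the only ping-pong
  statistic.
* TE expression takes transcript counts as given (no effective-length
  correction and no read-level quantification).
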