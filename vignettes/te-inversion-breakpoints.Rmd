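---
title: "Transposable elements at inversion breakpoints: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transposable elements at inversion breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teinv)
library(dplyr)
```

## The problem

Large chromosomal inversions arise mainly by two molecular routes, and each
leaves a different scar at the breakpoints:

* **Ectopic recombination** between two copies of the same transposable-element
  (TE) family sitting in inverted orientation. Misalignment and crossover
  between the copies inverts the intervening segment and leaves **two chimeric
  TE copies**, one spanning each breakpoint, whose halves derive from the two
  parental copies and therefore represent the *same portion of the family
  consensus* in opposite orientations.
* **Non-homologous end joining (NHEJ)** after two double-strand breaks.
  Re-ligation inverts the segment and typically leaves a **short inverted
  duplication of non-repetitive flanking DNA** at the junction.

`teinv` implements the breakpoint-centric analysis chain that discriminates
these signatures in assembly data: breakpoint interval estimation from
whole-genome alignments plus split reads, TE density enrichment statistics
around breakpoints, a resampling null for same-family TE co-occurrence in
region pairs, structural characterisation of MITE/TIR repeats, and a
nearest-signature mechanism classifier. The motivating system is the set of
four large polymorphic inversions of Atlantic cod (chromosomes 1, 2, 7 and
12), whose published breakpoint coordinate table ships with the package as
example data; all statistical machinery is general.

## Breakpoint estimation

An inversion shows up in a whole-genome alignment (PAF) as a maximal run of
minus-strand blocks flanked by plus-strand blocks. `call_inversions()` sorts
filtered blocks (default: blocks ≥ 5 kb, mapping quality ≥ 40) along the
target and reports the two **block gaps** around the minus run as breakpoint
intervals — ranges, never points, because the alignment only brackets the
junction. Two inversions closer than `min_gap` (default 100 kb) are reported
as one double inversion with a shared middle interval labelled B. A missing
anchor on one side yields an open-ended, flagged interval rather than a
silent drop.

`refine_with_clipped_reads()` tightens these ranges with split reads: a read
spanning a breakpoint aligns as exactly two opposite-strand segments, one at
each junction, and the segment boundary adjacent to the split (the clip) sits
on the breakpoint. The refined interval is the tightest span consistent with
all clips, intersected with the input interval — refinement never widens, and
contradictory clips flag a conflict instead of fabricating a range. With
error-free reads the interval collapses to ≤ 2 bp. For NHEJ inversions the
interval cannot collapse below the duplication length: the junction is
genuinely ambiguous across the duplicated block, and the refined width equals
`dup_len`, which is itself a useful diagnostic.

Interval widths are summarised with `summarize_intervals()` as `end - start`
on the coordinates as printed, and the SD uses the population divisor *n*.
Both conventions were fixed by checking that the bundled nine-range example
table reproduces its published summary (mean 16,862 bp, SD 21,417 bp) exactly;
the sample divisor would give ≈ 22,716.

Breakpoint *regions* for all downstream statistics are the interval midpoint
± 50 kb (100-kb windows), clamped and flagged at chromosome edges.
`project_syntenic_regions()` carries a region onto the non-inverted assembly
through the cross-alignment blocks; the outer boundaries of the projections
define the syntenic region, so a region straddling the inversion junction
legitimately projects to a wide interval.

## Density, centromeres, and enrichment tests

`density_track()` computes merged-coverage fractions per non-overlapping
window (50 kb by default; a terminal partial window is kept and flagged, and
is included in the background class by default). Coverage always merges
overlapping annotations — a base is covered or not — whereas the NTE50/LTE50
library metrics deliberately sum raw annotation lengths, because they
describe the annotation set ("number of largest TE copies"), not the genome.

Centromere-like regions are dense in repeats and would bias any
breakpoint-versus-background comparison, so `estimate_centromere()` flags
10-kb windows whose combined interspersed + tandem repeat density exceeds the
chromosome mean by `z_threshold` SDs (default 3) **or** that contain a hit of
a known centromeric repeat motif. The OR rule reflects that the two evidence
channels are complementary and individually reported; either alone is enough
to exclude a window from the statistics.

`ttest_enrichment()` is a two-sided pooled-variance Student's t-test of
window densities, breakpoint windows against all other non-excluded windows
of the same chromosome. A window belongs to the breakpoint class with ≥ 1 bp
of region overlap (configurable). Student's pooled form, not Welch, is the
default because it is the named test of the analysis this package
re-implements; Welch is available behind `welch = TRUE`. The mean-based t is
preferred over rank tests because window densities are zero-inflated and
median-based comparisons would be degenerate for rare TE groups. Degenerate
inputs are defined away explicitly: zero pooled variance with equal means is
t = 0, p = 1; with unequal means the result is flagged `degenerate` rather
than reported as an honest p-value. No multiple-testing correction is applied
by default (per-group raw p-values are reported); users can correct
downstream. `two_sd_peaks()` implements the descriptive complement: a
breakpoint region is "elevated" when its window-mean density strictly exceeds
the chromosome mean + 2 SD of non-excluded windows.

Calibration is a tested property, not an assumption: under uniform TE
placement the fraction of p < 0.05 over 400 simulated chromosomes must stay
inside the exact binomial 99% band around 0.05, and a planted contrast of
~6% breakpoint density against ~0.5% background (the magnitude of the
strongest MITE contrast in the motivating study) must be detected in ≥ 90%
of runs.

## The resampling null for shared families

Finding copies of the *same* family in both breakpoint regions of one
inversion is the key ectopic-recombination observation, so its null
distribution matters. `run_null()` draws `n_pairs` (default 1,000) random
non-overlapping region pairs per grid cell over region sizes 10–100 kb and
minimum copy lengths {0, 100, 500, 1000, 2000} bp, counting **distinct
families** with a qualifying copy in both members (1-bp overlap counts; copy
length is the full annotation length). Distinct-family counting is the
conservative reading of "TEs of the same family"; a `copy_pairs` statistic is
available. Pair members may not overlap each other, because real breakpoint
pairs are disjoint; the pair is drawn uniformly over exactly that
constrained space (two i.i.d. starts on the chromosome with one region's
footprint removed, sorted and spread), which is the distribution plain
rejection sampling converges to but terminates even in the forced-placement
case. `compare_observed()` attaches the real pair's count with the add-one
empirical p-value `(1 + #{mock ≥ obs}) / (n_pairs + 1)`, never exactly zero.
Centromere exclusion is off by default for the null and on for the t-tests;
both toggles are exposed.

The grid means are validated against exhaustive enumeration over a lattice of
start positions on a toy genome, to within 3 Monte-Carlo standard errors per
cell, and monotonicity (nonincreasing in minimum length, nondecreasing in
region size) is asserted on every run.

## Repeat structure: TIRs, tandem units, ORFs, consensus pileups

The matcher underlying all sequence-level comparison, `local_matches()`, is a
gap-free seed-and-extend dot-plot: exact 13-mer seeds grouped by diagonal,
merged within `max_gap` (100 bp), end-extended, with identity computed over
every column of the final span and both strands searched. Gap-free matching
(not affine-gap alignment) suffices because the 25%-identity screen it feeds
is deliberately coarse; an exact dynamic-programming aligner appears only as
a test oracle. Seeds occurring more than `max_occ` times are skipped to bound
work on hyper-repetitive input.

`self_structure()` reads a consensus' architecture off its self-dot-plot:

* **TIR**: the best opposite-strand self-match with the 5' arm at or before
  the 3' arm. A perfect palindrome returns both arms as one fragment, so the
  reported arm length is capped at half the span from 5'-arm start to 3'-arm
  end.
* **Tandem period**: the modal spacing between recurrences of exact 13-mers,
  requiring ≥ 3 supporting recurrences (guarding against dimer artifacts)
  and preferring the smallest mode when multiples tie — 167 wins over 334.
* **ORFs**: ATG-to-stop spans ≥ 100 aa in all six frames.

A MITE in this package's sense is exactly what `make_mite_consensus()`
builds: `TIR + linker + revcomp(TIR)` where the TIR is a tandem array of one
~167-bp unit, redrawn until no ORF of ≥ 50 codons survives — the
transposase-free, internally repetitive structure whose detection
(`tandem_period = 167`, TIR ≥ 450 of 501 bp, zero ORFs) is itself an
acceptance property. `consensus_coverage()` gives the per-position pileup of
genomic copies on a consensus; a zero-depth internal run is the footprint of
a lost transposase region.

Family assignment of consensus sequences follows the 80-80-80 rule (members
≥ 80 bp sharing ≥ 80% identity over ≥ 80% of the shorter sequence) and the
80-95-98 rule for subfamilies, as single-linkage clusters over pairwise
best local matches. Which of 95/98 is identity versus coverage is not fixed
by convention everywhere; here identity 95%, coverage 98%, both exposed as
arguments. Subfamily partitions provably refine family partitions under
these thresholds, and that property is tested.

## Mechanism classification

`find_inverted_duplications()` reports opposite-strand matches ≥ 300 bp at
≥ 80% identity within and between the two breakpoint regions, each scored by
the fraction of its two copies covered by TE annotations; below 0.2 it is
"non-TE-derived", the NHEJ signature. The 300-bp floor keeps seed-level noise
out while staying far below the worked 910-bp case. `ectopic_evidence()`
accepts a shared family when every breakpoint has a copy within 2 kb of the
interval, the near-breakpoint copies occur in both orientations, and the
copies' consensus sub-intervals overlap by ≥ 50% of the shorter — the
chimera geometry. `classify_mechanism()` then applies the nearest-signature
rule: the evidence class closer to the breakpoints wins; distances within a
5-kb tie margin give "ambiguous"; one class alone decides; none is
"no_signal". The 2-kb slop, 0.2 TE-overlap threshold and 5-kb tie margin are
package choices calibrated against the one quantitative anchor available — a
non-TE duplication 23 kb from a breakpoint must lose to TE evidence at the
breakpoint — and all are arguments, not constants.

## The synthetic-genome generator

`simulate_inversion_scenario()` is first-class, tested code and defines the
study conditions for every stochastic acceptance property. It emulates:

* an i.i.d. background genome (GC 0.45 by default);
* a MITE family with 501-bp TIRs of 167-bp tandem units and a ~120-bp linker;
* background families inserted as old, fragmented copies — random 300–900 bp
  portions of a 1.5-kb consensus at elevated divergence — so that, as in real
  genomes, long (≥ 1 kb) same-family copies are rare outside breakpoints;
* ectopic scenarios: two inverted-orientation MITE partners at ~30% and ~70%
  of the chromosome with crossover at the consensus midpoint, each with an
  intact companion copy ~2 kb away (the tandem arrangement seen at real
  TE-mediated breakpoints, and the reason each breakpoint region retains a
  full-length ≥ 1-kb copy after the partners become chimeras);
* NHEJ scenarios: breakpoints nudged off all TE copies, with an inverted
  duplication of the `dup_len` (default 910) bases upstream of the first
  breakpoint inserted at the second junction — giving a plus-strand copy near
  breakpoint 1 and its reverse complement near breakpoint 2, which is the
  between-region opposite-strand signal the detector looks for;
* optional centromere-like block: a 40-kb tandem array of a 158-bp unit at
  mid-chromosome, annotated as a Satellite family;
* exact truth alignments (forward–reverse–forward PAF, with a target-side gap
  for the NHEJ duplication) and breakpoint-spanning reads with exact
  split-segment truth.

One RNG stream per scenario is split into tagged sub-seeds (background,
consensus, each placement round, geometry, reads), so partial pipelines stay
reproducible and any stage can be re-derived in isolation. The generator's
narrative direction for reads follows the read-mapping design of the
analysis it supports: reads are drawn from one haplotype and their exact
split alignments reported on the other; segment coordinates are emitted in
the derived frame, which for length-conserving inversions coincides with the
ancestral frame numerically.

What the generator does **not** emulate — and what green tests therefore do
not certify about real data: indels and realistic long-read error profiles
(substitutions only), nested or fragmented TE insertions beyond simple
sub-interval copies, segmental duplications other than the planted NHEJ one,
GC heterogeneity and repeat-induced mis-assembly, and aligner artefacts
(truth alignments are exact, so breakpoint recovery rates measure the
calling logic, not minimap2's behaviour).

## Problem sizes and numerical choices

The bundled test and acceptance runs use deliberately scaled problem sizes:
breakpoint recovery over 50 seeded scenarios on 1–5 Mb genomes; mechanism
accuracy over 100 scenarios on 0.5-Mb genomes (the 100-kb breakpoint regions
dominate the cost, not the chromosome); enrichment calibration over 400
2-Mb chromosomes; the resampling-null genome for the long-TE contrast is
5 Mb so that, as on real chromosomes, a 100-kb region is a small fraction of
the whole. Ties among overlapping alignment blocks are broken by match count
then length; empty block gaps become 2-bp intervals around the junction so an
interval is never a point; p-values are floored at the smallest positive
double rather than reported as 0.

## Known limitations

* The inversion caller models inversions and inverted duplications only — no
  translocations, no duplicative transposition, no full structural-variant
  taxonomy.
* Read refinement consumes pre-computed alignment segments (PAF); it does not
  parse CIGAR strings or BAM.
* `local_matches()` is gap-free; strongly indel-diverged copies fragment into
  several collinear matches, which downstream consumers tolerate but which
  underestimates single-copy identity.
* The mechanism classifier is validated on simulations; on real assemblies
  its evidence lists should be inspected, not consumed blindly — the
  `mechanism_call` object retains both full evidence tables for exactly that
  reason.
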