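---
title: "Methods: linkage-map chromosome building, inversion localization and centromere scanning"
author: "chromforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage-map chromosome building, inversion localization and centromere scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromforge)
```

# Scope and model

`chromforge` implements a comparative-genomics workflow for organisms with a
dense SNP linkage map and a long-read contig assembly, such as Atlantic cod
(*Gadus morhua*, 2n = 46, 23 linkage groups):

1. **Chromosome building.** SNP markers with known sex-specific genetic
   positions (cM) are located on contigs by their flanking sequence;
   contigs are assigned to linkage groups by marker vote, chimeric contigs
   are detected and broken, and the remainder are ordered and oriented by
   genetic position and concatenated into chromosome sequences (FASTA +
   AGP).
2. **Inversion localization.** Two chromosome-level genomes are compared
   through unique k-mer anchors chained into strand-consistent synteny
   blocks; runs of reverse-strand blocks flanked by forward blocks are
   called as inversions, and each breakpoint is reported as the interval
   between the last co-linear anchor and the first inverted anchor.
3. **Centromere-candidate scanning.** Tandem-repeat arrays are detected (or
   imported from Tandem Repeats Finder), filtered for centromere-like
   properties (strictly more than 60% AT, unit strictly longer than 80 bp),
   clustered into families at 95% identity, and tested for presence on all
   chromosomes.
4. **Recombination profiles.** Windowed cM/Mb rates locate
   recombination-suppressed regions; chromosomes whose suppressed region is
   central are classified metacentric (the sigmoidal bp-vs-cM profile), and
   suppression is tested for co-location with satellite density.

A synthetic-genome generator plants every structure the pipeline detects,
with recorded ground truth, so all claims are tested end to end without any
external download.

# The synthetic study system

The generator's defaults describe a desk-scale analog of the real system,
chosen once and used by every test:

| Parameter | Default | Rationale |
|---|---|---|
| chromosomes | 23 × 2 Mb | the real karyotype count at ~1/15 linear scale, so a full run takes minutes |
| GC fraction | 0.46 | teleost-typical base composition |
| marker density | 100 / Mb | same marker-per-chromosome order as a 9k-SNP map over 23 chromosomes |
| contig mean length | 250 kb | reproduces the real contig:chromosome length ratio (~0.5 Mb contigs on ~28 Mb chromosomes) |
| chimera rate | 0 (0.01 in the anchoring study) | the real assembly contained 2 chimeras in 1,253 contigs |
| F:M map expansion | 1.3 | the measured heterochiasmy of the real map (1,662.7 / 1,262.3 cM) |
| male map / chromosome | 55 cM | 1,262.3 cM spread over 23 linkage groups |
| SNP divergence | 0.002 | stresses anchoring the way two conspecific assemblies do |
| centromeric element | 88 + 82 + 88 bp, 70% AT | the unit–spacer–unit satellite structure, safely past the >60% AT filter |
| copies per array | 20, 2% per-copy mutation | exercises clustering at the 95% identity threshold |
| suppression window | 400 kb | pericentromeric recombination suppression extends far beyond the physical array |
| decoy arrays | AT-rich 120 bp arrays on 3 chromosomes | a repeat family that passes the AT/length filter but must fail the all-chromosomes test |

Base composition is i.i.d. apart from the planted arrays (an optional
salt-and-pepper repeat background exists, off by default): this keeps
unique-k-mer anchoring well-posed at desk scale. Real genomes have
repeat-rich backgrounds that erode anchor density; the PAF import path
exists so that real alignments (LASTZ, minimap2) can drive the inversion
caller instead.

Marker cM positions integrate a piecewise recombination-rate profile that
is zero inside the suppression window and constant elsewhere; the female
map is the male map scaled by the expansion factor. Markers falling inside
planted inversions keep the cM of the non-inverted arrangement, as a map
estimated in a population segregating for the inversion would. Chimeric
contigs join fragments of two chromosomes with no junction signature —
they are detectable only through their markers, as in the real study.

The **double inversion** is modeled as two serial inversions sharing a
boundary (`[p1, p2)` then `[p2, p3)`), which produces three breakpoints.
Its dot-plot signature, and the detection rule, is a run of
reverse-strand blocks in which consecutive blocks *ascend* on the target:
a single inversion traversed left to right descends on the target, so an
ascending junction inside an inverted run implies a second serial event.
Nested or deeper rearrangements are outside the model and are reported as
singles.

# Numerical and design choices

**Coordinates.** All internal coordinates are 0-based half-open. Reports
use 1-based starts with `size = end - start`; the end-exclusive
subtraction mirrors the breakpoint-interval convention of the comparative
table this report reproduces, where printed sizes equal `end - start`
exactly. The outer inversion span is `(last end - first start) / 1e6`
rounded to two decimals. One published row is internally inconsistent with
its own coordinates — its span prints 4.51 Mb where the subtraction gives
4.50, and its second interval prints 4,840 bp where the subtraction gives
4,845 — and the report sides with the arithmetic in both places.

**Breakpoint identifiability.** A rearrangement junction flanked by j
bases that coincidentally match the co-linear continuation produces a
sequence identical to the same rearrangement shifted by up to j bases, so
junction coordinates are only defined up to this micro-homology. Exact-
match anchors absorb those bases; recovery tests therefore score
truth-breakpoint containment with an 8 bp equivalence slack (the
coincidence tail decays as 4^-j), while reported intervals keep the pure
between-anchors definition.

**Marker placement.** Exact search of the concatenated flanks on both
strands of every contig (Aho–Corasick over all markers simultaneously),
with the SNP site at the flank junction. Zero exact hits fall back to a
seeded search: the leftmost 31-mer of the concatenated flank is located
exactly and the full flank verified allowing ≤ 2 mismatches. More than one
hit anywhere marks the marker ambiguous; ambiguous and absent markers
never vote. This replaces an alignment-tool dependency with a
deterministic method of equivalent behavior on conspecific data; users
with divergent data can import placements computed externally.

**Chimera detection and breaking.** A contig is chimeric when two linkage
groups each contribute at least `minVotes = 2` placed markers — a single
discordant marker is placement noise. This evidence threshold is also the
detectability limit: a chimeric join whose minor part carries fewer than
two markers is invisible to any map-based method, and the recovery tests
score only detectable chimeras while requiring zero false breaks. The
breakpoint is the midpoint between the last marker of the 5' group and the
first of the 3' group, the map's resolution limit (the original study
localized its two chimeric breakpoints with a second assembly, a resource
the pipeline does not assume). Interleaved label patterns (> 10%
discordance after the best two-segment split) drop the contig from
anchoring.

**Ordering and orientation.** Contigs sort by mean female cM (the longer,
denser map), tie-broken by mean male cM then contig id. Orientation is the
sign of Kendall's tau between marker bp and cM, asserted only when
`|tau| >= 0.5` and two distinct cM values exist; otherwise the contig is
emitted forward and flagged. Gap length between contigs is a fixed 500 N
(configurable); nothing in the data constrains it.

**Anchoring and chaining.** Anchors are maximal runs of k-mers (k = 21,
odd so no k-mer is its own reverse complement) that occur exactly once in
each genome counting both strands. Chaining is best-first extraction of
maximum-weight co-linear chains (weight = summed anchor length) by exact
O(n²) dynamic programming per extraction; anchors may chain when they
share a strand and both same-genome gaps lie in [0, maxGap = 100 kb].
Chains under 20 kb query span or 5 anchors are discarded. The extraction
is verified against exhaustive subset enumeration on small instances.
Blocks nested inside a same-strand block (secondary chains shed around
repeat arrays) are dropped before inversion calling.

**Tandem detection.** A simplified seed-and-extend detector: a position
seeds period p when its 15-mer recurs at lag p in [50, 600]; loci extend
copy by copy while consecutive copies agree at 80% (ungapped), with
sub-period boundary refinement for partial copies, per-column majority
consensus, and primitive-period reduction (a lag that is a multiple of the
physical period is collapsed to its smallest self-consistent divisor).
Overlapping calls keep the larger `copy_number × period`, ties to the
smaller period. The detector assumes a substitution-only mutation model;
indel-rich real satellites should be imported from Tandem Repeats Finder
`.dat` output, for which a parser is provided.

**Family clustering and counting.** Greedy centroid clustering in
decreasing array-mass order; identity between consensi is maximized over
cyclic rotations (tandem phase is arbitrary) and both strands, by cyclic
Hamming identity for equal lengths and global alignment otherwise.
Occurrence counting is a seeded ungapped semi-global scan: with a 13-mer
seed, any placement at ≥ 95% identity of a ≥ 88 bp unit must contain an
exact seed on the matching diagonal (pigeonhole), so the seeded scan
provably equals the brute-force all-offsets scan it is tested against.
The reported monomer is the full unit–spacer–unit element;
`detectSubunit()` exposes the internal sub-unit (the two near-identical
terminal repeats found by self-comparison) for analyses that want the
88 bp monomer instead.

**Recombination profiles.** cM is linearly interpolated between markers
and differenced over fixed windows (100 kb at desk scale). Monotonicity
violations ≤ 0.5 cM are clamped as map noise; larger ones are input
errors. A suppressed region is the longest run of windows below 0.2 × the
chromosome's median rate — a convention, not a measured constant, exposed
as a parameter. Metacentric means the suppressed midpoint falls in the
central half of the chromosome. Co-location of the suppressed region with
the satellite-density peak is evidence, not ground truth: inversions also
suppress recombination, so a suppressed region need not be the centromere,
and the classifier is deliberately reported alongside the density track
rather than folded into it.

# What passing tests do and do not show

The synthetic genomes are easier than real data in specific, known ways:
no indels between the genome pair, no dispersed repeat background by
default, no genotyping error in the map, and exponential contig lengths
with exact flank fidelity. Passing recovery tests therefore demonstrates
the correctness of the algorithms under their stated models — exact
breakpoint bracketing, exact family recovery, exact chain optimality — not
performance on a real assembly. The interop paths (PAF alignments,
TRF `.dat`, externally computed placements) are the intended entry points
for real data, and the desk-scale defaults (problem sizes of 23 × 2 Mb,
chosen so that a full pipeline run completes in minutes) scale linearly in
genome length.

# Worked example

```{r example, eval = FALSE}
cfg <- SimConfig(seed = 1, chimeraRate = 0.01)
cfg@inversionSpecs <- defaultInversionSpecs(cfg)
sim <- simulateGenomePair(cfg)

## chromosome building from contigs + markers
bld <- buildChromosomes(sim$contigs, sim$markers)
bld$stats$fraction_of_assembly

## inversion calling against the reference genome
anchors <- findUniqueAnchors(sim$query, sim$reference)
blocks <- chainAnchors(anchors)
calls <- callInversions(blocks)
reportTable2(calls)

## centromere candidates and morphology
arrays <- detectTandemArrays(sim$query)
cands <- centromereCandidates(arrays, nChroms = 23)
co <- countOccurrences(sim$query, cands$families$consensus[1])
```

The acceptance script (`scripts/acceptance.R`) runs this workflow from
scratch at the full desk scale and writes every recovered quantity to
JSON; see the README for how to run and read it.
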