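---
title: "Methods: DNase hypersensitivity dynamics across differentiation stages"
author: "dhsdyn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNase hypersensitivity dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsdyn)
```

# Scope and model

`dhsdyn` analyses DNase-seq open-chromatin peaks across an ordered series of
differentiation stages, each profiled in two biological replicates. The
package operates strictly downstream of read alignment and peak calling:
its inputs are per-replicate peak calls (BED), per-stage normalized coverage
(bedGraph), a gene annotation, optional TF ChIP peak sets, and an expression
table. Its outputs are the stage-level summaries a chromatin-dynamics study
reports: consensus site counts, a stage Venn over a merged-union site
universe, gained/lost site calls with loss/gain ratios, genomic partition
tabulations, DHS x TF co-occupancy, TES-flank signal profiles with gene
grouping, and a cross-tabulation of those groups against expression classes.

Coordinates are BED-convention 0-based half-open at every file boundary and
1-based closed `GRanges` internally; the conversion happens only in I/O
code. "Overlap" always means at least one shared base (configurable via
`min_overlap_bp`): the analyses this package reproduces state no
reciprocal-fraction requirement, so any-bp is the defensible default and a
knob, not a constant.

## Replicate consensus

Peak calls present in only one replicate are treated as false-positive calls
and removed. Operationally, `replicateConsensus()` forms the connected
components of mutually *overlapping* rep1/rep2 intervals (book-ended calls,
which share zero bases, do not connect) and emits the merged span of every
component containing at least one interval from each replicate. Emitting the
merged span — rather than the rep1 or rep2 interval alone — reflects the
view that the retained site spans the called peaks of both samples; it also
makes the consensus well-defined when one replicate fragments a site that
the other calls in one piece.

## The site universe and stage Venn

Counting "unique sites" across stages requires de-duplicating
boundary-shifted peaks. `stageVenn()` operationalizes the universe as the
merged union (gap 0; book-ends merge, so a site split at a bin boundary
counts once) of all stage consensus sets, then flags each universe region
per stage it overlaps. This makes the pattern counts a partition of the
universe — an invariant re-checked on every pipeline run — at the cost of
letting one wide region absorb several narrower stage-specific calls; the
per-stage gained/lost calls are therefore computed on each stage's own
consensus intervals, not on universe regions, and both views are emitted.

## Gained and lost sites

`differentialSites(from, to)` calls a from-interval *lost* when it overlaps
nothing in the to-stage and a to-interval *gained* symmetrically. The
conservation identities `n_lost + n_shared_from = |from|` and
`n_gained + n_shared_to = |to|` hold by construction and are asserted at run
time; a transition that gains nothing yields a flagged-undefined (`NA`)
loss/gain ratio rather than an error. Percentages are reported half-up at
one decimal (`percentOf()`), matching how such shares are conventionally
printed; the half-up rule is guarded against binary representation error
just below a `.5` boundary.

## Genomic partitions

`buildPartitions()` derives six footprints from the collapsed gene models:
promoter, coding exon, all introns, first introns, later introns, and
intergenic. Two choices here are genuinely open and therefore exposed as
parameters rather than hard-coded:

* **Promoter window** (`promoter_up = 2000`, `promoter_down = 500` bp,
  strand-aware, clamped at chromosome edges): a common regulatory-genomics
  convention; sensitivity to it is exactly what the knob exposes.
* **Isoform collapsing**: one model per gene via the longest transcript
  (`collapse = "longest"`), since partition tabulations are reported at gene
  level; per-transcript models remain available.

"Coding exon" means every annotated exon of the collapsed model — the input
table need not carry CDS/UTR structure, and no CDS distinction is made.
First introns are defined in transcription order (the gap adjacent to the
highest-coordinate exon on the minus strand). Categories are deliberately
*not* complemented against each other: a nested gene's exon may sit in
another gene's intron and both categories then cover the same bases; only
`intergenic` is the genome complement of merged gene bodies plus promoters.
Consequently a large site can be tabulated in several categories
(`classifyPeaks()` reports the per-peak flag matrix for downstream joins),
and per-category counts sum to at least the peak count.

## Regulome overlap

`regulomeOverlap()` flags each consensus DHS site as runx2-only, ctcf-only,
both, or neither (Venn semantics: a site hit by both factors counts once
under `both`, and multiple TF peaks in one site count as one event). Because
the co-occupancy question is asymmetric, TF-side fractions (share of TF
peaks inside vs outside any DHS) are reported alongside the DHS-side ones.

## Signal profiles and TES-flank groups

Coverage arrives as bedGraph in normalized units and is binned at
`bin_bp = 25` bp (bin value = mean of per-base sums over the bin; the last,
possibly partial, bin averages only in-genome bases). 25 bp resolves the
±250 bp classification tolerance with ten bins per window while keeping a
3 Mb chromosome at 120k bins. `maskToPeaks()` zeroes every bin not touching
a consensus site, mirroring the practice of profiling only reads that fall
in replicate-supported peaks — this removes background noise and
false-positive signal before aggregation.

`tesProfile()` extracts TES ± 2 kb per gene in transcription orientation
(minus-strand rows are flipped so positive offsets are always downstream);
column offsets are bin centers relative to the TES, and the per-gene summit
is the *leftmost* bin attaining the row maximum — a deterministic tie-break
that also sends all-zero rows to the far-upstream offset, which can never
classify as downstream. `metageneProfile()` rescales gene bodies onto 100
equal-length segments so genes of different lengths align column-wise, with
native-bin flanks.

`classifyTesFlank()` assigns a gene to the group whose window
`[center − tolerance, center + tolerance]` (defaults: centers 500 and
1000 bp, tolerance 250 bp; touching window edges resolve to the lower
center) contains its summit offset, provided the summit is strictly
downstream and passes a minimum-summit rule. The minimum-summit rule is the
one genuinely open operationalization in this module, and the package
default is a **per-gene prominence criterion**: the summit must reach
`minSummitRatio` (default 3) times the gene's own row median (or simply be
positive when the median is zero). A cohort-quantile threshold
(`minSummitQuantile`) and an absolute floor (`minSummit`) are also
available. The prominence rule is preferred as the default because it is
scale-free and independent of cohort composition: a quantile threshold
presumes that most profiled genes lack a flank bump, which holds in
genome-wide cohorts but fails badly when the profiled set is enriched for
bump-carrying genes (as in the package's own validation cohorts, where half
the genes carry planted bumps — there a 75th-percentile threshold would
land inside the signal distribution and reject half the true positives).

## Expression classes

`foldChangeClasses()` classifies genes by the pseudocounted ratio
`(b + 1)/(a + 1)` with an *inclusive* two-fold boundary (an exactly two-fold
change counts as changed), replacing upstream cluster-node selection — which
is visualization-driven and under-specified — with the explicitly stated
fold-change criterion. The pseudocount (default 1, in the linear expression
units of the input) guards zero denominators; swapping the stages maps UP to
DOWN exactly. `crossTabulate()` counts (class × TES group) cells over the
intersection of the two gene universes and reports the intersection size;
margins are re-checked against the input class sizes at run time.

# The synthetic-data generator

`generateSynthetic()` plants ground truth for every downstream stage on a
toy genome (default 2 × 3 Mb). Its defaults encode the study conditions the
pipeline is meant to operate under:

* **Replicate concordance 0.45** — roughly 40–50% of replicate-1 calls
  supported by replicate 2, the regime reported for conservative dual-
  replicate DNase-seq selection.
* **Stage membership fractions** mirroring observed three-stage Venn
  proportions: ~0.34 of the universe common to all three stages,
  stage-exclusive fractions ~0.21/0.07/0.08 (earliest stage most
  accessible), remainder split evenly among pairwise patterns.
* **Site lengths** log-normal with 400 bp median (sdlog 0.6), clamped to
  [50 bp, 20 kb] — most sites a few hundred bp with a long upper tail.
* **TF co-occupancy** 22.6% runx2-only / 16% ctcf-only / 10% both of a
  stage's sites (allocated by largest remainder, so planted fractions are
  recovered exactly), with 37% of RUNX2 and 30% of CTCF peaks placed
  outside any site.
* **TES cohort** 200 genes: 50 planted with a +500 bump, 50 with +1000,
  100 flat. Bump genes receive a dedicated flank site (width 600 bp,
  centered at the planted offset, concordant in every stage), so the bump
  survives peak masking exactly as real TES-flank hypersensitivity would.
* **Expression** UP↔+1000 and DOWN↔+500 at fidelity 0.9, with planted
  linear folds 4 and 0.25 (comfortably past the inclusive two-fold boundary
  after pseudocounting) and UNCHANGED folds within ±0.4 log2 units.
* **Coverage** triangular kernels over each stage's realized sites (apex at
  the site midpoint, height ∝ site score) plus i.i.d. per-bin uniform
  background noise of amplitude 0.25 against bump height 1.0.

Planted sites keep ≥ 30 bp clearance (plus twice the ±10 bp replicate edge
jitter), so merged-union counting can never fuse distinct truth sites, and
background sites avoid all TES ± 2.6 kb windows so the flank classification
has a clean truth. One seed drives six documented sub-seeds (genes, groups,
sites, replicates, TFs, tracks); identical seeds give byte-identical file
bundles.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level sampling noise (coverage is a smooth
kernel, not resampled reads), irregular peak shapes and shoulders,
copy-number or mappability artifacts, chromosome-scale domain structure,
overlapping or bidirectional genes near TES windows, and expression
measurement error beyond the planted fidelity. Recovery rates on this
generator are upper bounds on real-data behavior; the oracle tests (per-base
bitmap and all-pairs scans on ≤ 10 kb toy genomes) are exact regardless.

# Numerical choices and degenerate inputs

* Merging at `gap = 0` joins book-ended intervals (a site split by a caller
  boundary counts once); the consensus component step, by contrast, requires
  a genuinely shared base. Both behaviors are fixed by the half-open
  convention, not by tolerances.
* Summit ties break leftmost; classification windows touching at one point
  resolve to the lower center; summit offsets are bin centers, so a planted
  apex is recovered within half a bin.
* Empty inputs degrade softly with warnings (empty replicate → empty
  consensus; empty TF set → zero fractions; empty partition category → NA
  summaries); malformed files fail fast with the offending line number.
* Percent rounding is half-up at one decimal with an epsilon guard;
  fold-change boundaries are inclusive.
* Genes whose TES flank leaves the chromosome, or whose body is shorter
  than the number of metagene segments, are dropped with a warning rather
  than silently padded.

# Problem sizes

The shipped validation suite runs the full pipeline on the default design
(2 × 3 Mb genome, 500 planted sites, 200 genes) plus smaller 1-chromosome
variants, and checks interval operations against per-base oracles on 100
random ≤ 10 kb toy genomes; these sizes give exact, fast, deterministic
checks of every code path while remaining far below genome scale. Counts
produced at this scale are study-shaped, not study-sized: genome-scale
magnitudes (hundreds of thousands of sites) depend on the underlying
sequencing data and are not reproduced here.

# Limitations

Beyond the generator's idealizations listed above: the package does not
assess statistical significance of overlaps (no permutation or
hypergeometric testing of co-occupancy — raw counts and fractions only),
does not model differential-expression variance (threshold classification
only), and treats the annotation's collapsed gene model as the unit of
analysis. The TES-group definition is an explicit operationalization
(window centers, tolerance, summit rule) of a qualitative observation;
group sizes are sensitive to those parameters by design, which is why every
one of them is exposed in the configuration.
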